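# Reactive atom per residue type: first listed atom present in the residue
# wins; later names are ordered fallbacks. User-overridable per run.
SER OG
THR OG1
TYR OH
CYS SG
LYS NZ
ARG NH1
HIS NE2 ND1
ASP OD1 OD2
GLU OE1 OE2
ASN OD1
GLN OE1
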