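# Heavy-atom charge (e) / radius (A) table for continuum electrostatics.
# PARSE-inspired: hydrogens are folded into neighbouring heavy atoms so that
# each residue sums exactly to its formal charge at pH 7 (Asp/Glu -1,
# Lys/Arg +1, His 0, others 0), while canonical charges on reactive polar
# atoms are preserved (e.g. Ser OG -0.49 with the compensation on CB).
# residue "*" = backbone entries shared by all amino acids.
# residue	atom	charge	radius
*	N	0.00	1.50
*	CA	0.00	1.70
*	C	0.55	1.70
*	O	-0.55	1.40
*	OXT	0.00	1.40
ALA	CB	0.00	1.70
ARG	CB	0.00	1.70
ARG	CG	0.00	1.70
ARG	CD	0.00	1.70
ARG	NE	0.00	1.50
ARG	CZ	0.10	1.70
ARG	NH1	0.45	1.50
ARG	NH2	0.45	1.50
ASN	CB	0.00	1.70
ASN	CG	0.55	1.70
ASN	OD1	-0.55	1.40
ASN	ND2	0.00	1.50
ASP	CB	0.00	1.70
ASP	CG	0.14	1.70
ASP	OD1	-0.57	1.40
ASP	OD2	-0.57	1.40
CYS	CB	0.33	1.70
CYS	SG	-0.33	1.85
GLN	CB	0.00	1.70
GLN	CG	0.00	1.70
GLN	CD	0.55	1.70
GLN	OE1	-0.55	1.40
GLN	NE2	0.00	1.50
GLU	CB	0.00	1.70
GLU	CG	0.00	1.70
GLU	CD	0.14	1.70
GLU	OE1	-0.57	1.40
GLU	OE2	-0.57	1.40
HIS	CB	0.00	1.70
HIS	CG	0.00	1.70
HIS	ND1	0.10	1.50
HIS	CD2	0.00	1.70
HIS	CE1	0.30	1.70
HIS	NE2	-0.40	1.50
ILE	CB	0.00	1.70
ILE	CG1	0.00	1.70
ILE	CG2	0.00	1.70
ILE	CD1	0.00	1.70
LEU	CB	0.00	1.70
LEU	CG	0.00	1.70
LEU	CD1	0.00	1.70
LEU	CD2	0.00	1.70
LYS	CB	0.00	1.70
LYS	CG	0.00	1.70
LYS	CD	0.00	1.70
LYS	CE	0.00	1.70
LYS	NZ	1.00	1.50
MET	CB	0.00	1.70
MET	CG	0.00	1.70
MET	SD	0.00	1.85
MET	CE	0.00	1.70
PHE	CB	0.00	1.70
PHE	CG	0.00	1.70
PHE	CD1	0.00	1.70
PHE	CD2	0.00	1.70
PHE	CE1	0.00	1.70
PHE	CE2	0.00	1.70
PHE	CZ	0.00	1.70
PRO	CB	0.00	1.70
PRO	CG	0.00	1.70
PRO	CD	0.00	1.70
SER	CB	0.49	1.70
SER	OG	-0.49	1.40
THR	CB	0.49	1.70
THR	OG1	-0.49	1.40
THR	CG2	0.00	1.70
TRP	CB	0.00	1.70
TRP	CG	0.00	1.70
TRP	CD1	0.00	1.70
TRP	CD2	0.00	1.70
TRP	NE1	0.00	1.50
TRP	CE2	0.00	1.70
TRP	CE3	0.00	1.70
TRP	CZ2	0.00	1.70
TRP	CZ3	0.00	1.70
TRP	CH2	0.00	1.70
TYR	CB	0.00	1.70
TYR	CG	0.00	1.70
TYR	CD1	0.00	1.70
TYR	CD2	0.00	1.70
TYR	CE1	0.00	1.70
TYR	CE2	0.00	1.70
TYR	CZ	0.49	1.70
TYR	OH	-0.49	1.40
VAL	CB	0.00	1.70
VAL	CG1	0.00	1.70
VAL	CG2	0.00	1.70
ZN	ZN	2.00	1.39
MG	MG	2.00	1.18
MN	MN	2.00	1.40
CA	CA	2.00	1.71
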