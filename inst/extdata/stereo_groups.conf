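# Stereochemically equivalent side-chain groups used to relax motif sites.
# Singleton "<Xxx>only" groups for every amino acid are added automatically.
Sergrp: SER THR TYR CYS
Lysgrp: LYS ARG HIS
Aspgrp: ASP GLU
Hisgrp: HIS
Asngrp: ASN GLN ASP GLU
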