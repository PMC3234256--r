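PDB ID,SITE NUMBER,RESIDUE TYPE,CHAIN ID,RESIDUE NUMBER,CHEMICAL FUNCTION,EVIDENCE TYPE,LITERATURE ENTRY
9trp,0,SER,A,195,Nucleophile,LIT,9ref
9trp,0,HIS,A,57,Proton acceptor,LIT,9ref
9trp,0,ASP,A,102,Electrostatic stabiliser,LIT,9ref
9lac,0,SER,A,70,Nucleophile,LIT,9ref
9lac,0,LYS,A,73,Proton acceptor,LIT,9ref
9lac,0,SER,A,130,Proton shuttle,LIT,9ref
9lac,0,LYS,A,234,Electrostatic stabiliser,LIT,9ref
9hom,0,SER,A,70,Nucleophile,PSI-BLAST,9lac
9hom,0,LYS,A,73,Proton acceptor,PSI-BLAST,9lac
9hom,0,SER,A,130,Proton shuttle,PSI-BLAST,9lac
9big,0,SER,A,10,Nucleophile,LIT,9ref
9big,0,HIS,A,20,Proton acceptor,LIT,9ref
9big,0,ASP,A,30,Electrostatic stabiliser,LIT,9ref
9big,0,GLU,A,40,Electrostatic stabiliser,LIT,9ref
9big,0,LYS,A,50,Electrostatic stabiliser,LIT,9ref
9big,0,TYR,A,60,Electrostatic stabiliser,LIT,9ref
9dim,0,SER,A,15,Nucleophile,LIT,9ref
9dim,0,HIS,B,25,Proton acceptor,LIT,9ref
9dim,0,ASP,A,35,Electrostatic stabiliser,LIT,9ref
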