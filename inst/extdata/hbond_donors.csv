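# hydrogen-bond donor heavy atoms; "*" matches any residue name
residue_name,atom_name
*,N
SER,OG
THR,OG1
TYR,OH
LYS,NZ
ARG,NE
ARG,NH1
ARG,NH2
ASN,ND2
GLN,NE2
HIS,ND1
HIS,NE2
TRP,NE1
HOH,O
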