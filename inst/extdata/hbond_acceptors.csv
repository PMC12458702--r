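# hydrogen-bond acceptor atoms; "*" matches any residue name
residue_name,atom_name
*,O
*,OXT
ASP,OD1
ASP,OD2
GLU,OE1
GLU,OE2
ASN,OD1
GLN,OE1
SER,OG
THR,OG1
TYR,OH
HIS,ND1
HIS,NE2
HOH,O
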