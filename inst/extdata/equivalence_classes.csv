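# chemically equivalent side-chain atoms averaged in persistence tables
residue_name,atom_name,class_name
ASP,OD1,ODx
ASP,OD2,ODx
GLU,OE1,OEx
GLU,OE2,OEx
ARG,NH1,NHx
ARG,NH2,NHx
PHE,CD1,CDx
PHE,CD2,CDx
PHE,CE1,CEx
PHE,CE2,CEx
TYR,CD1,CDx
TYR,CD2,CDx
TYR,CE1,CEx
TYR,CE2,CEx
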