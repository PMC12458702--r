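# basic (cationic) nitrogen atoms for salt-bridge detection
residue_name,atom_name
LYS,NZ
ARG,NH1
ARG,NH2
ARG,NE
HIS,ND1
HIS,NE2
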