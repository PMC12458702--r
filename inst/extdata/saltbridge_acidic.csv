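# acidic (anionic) oxygen atoms for salt-bridge detection
residue_name,atom_name
ASP,OD1
ASP,OD2
GLU,OE1
GLU,OE2
*,OXT
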