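sample	n_somatic	enrichment
S7	115	No
S12	63	G4 strong
P1	87	No
P14	234	No
P20	182	No
P22	191	No
P23	119	G4 strong
P30	662	No
P34	267	No
P37	82	G4 strong
P48	227	G4 weak + G4 strong
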