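sample	sex	age	paraprotein	stage	performance
S7	M	81	IgG k	I	ECOG II
S12	F	61	IgG l	II	ECOG II
P1	F	74	IgG k	II	ECOG II
P14	F	58	IgA k	I	ECOG I
P20	M	74	IgG k	III	ECOG III
P22	F	71	IgA l	I	ECOG I
P23	F	73	IgG k	I	ECOG I
P30	M	69	IgG k	III	ECOG II
P34	M	83	IgG k	II	ECOG II
P37	M	64	IgA l	II	ECOG III
P48	F	56	IgG k	III	ECOG III
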