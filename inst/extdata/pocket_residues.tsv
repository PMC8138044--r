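chain	resno	resid
A	37	VAL
A	38	MET
A	39	PRO
A	40	ALA
A	41	PHE
A	42	LEU
A	43	LEU
A	119	TYR
A	121	ALA
B	217	VAL
B	218	PHE
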