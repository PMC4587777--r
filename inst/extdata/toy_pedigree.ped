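FAM1	FA	0	0	1	1
FAM1	MO	0	0	2	1
FAM1	P1	FA	MO	2	2
FAM1	S1	FA	MO	1	1
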