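sample	expected_level	condition	replicate
titr_L000	0	C1	1
titr_L025	25	C1	1
titr_L050	50	C1	1
titr_L075	75	C1	1
titr_L100	100	C1	1
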