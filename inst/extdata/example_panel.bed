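amp01	0	250	amp01	0	+	20	20
amp02	0	250	amp02	0	+	20	20
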