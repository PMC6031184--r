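>amp01
AAAACTCCATGTGTAACTCCAGAACGAGAATCTTGCACTCTGCCTTTCCATATCTCATGAACCCCCTGCACACCCTAAAG
TACAATTAGGACGTTCATCCCTACACTGTATATGCCTAACTTTCTAATAAACAACTTAGCAACAAGTCACCTAGAAACGT
ACCACTGGCATATCACTCCTCCCACTTGCCATCTTCAACTTCATGACCCTCATGCATCACAAAGCGTCAAGCCTGAGTCT
AGGCTTTGAA
>amp02
CATGTGAATACATGAGTCTTCAGACGGCAGTTGAATATCTAACTACCCCTGCTCAAGGACACACTAGTCACCCTTGAGAG
CACTCCAGTCCCGGCAAGGTATCCACAACTATACAACTCAGCTAGCAAACACTCAGTTTATCTATGCAGCTAATATCCGT
AGTAGTCAACCCCTGAGATGACCAGTCATCAGGCTGCATCCTACTCACCAACTGCTCCTACAGACGCATGCTACCTGACC
ATGCAACTCA
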