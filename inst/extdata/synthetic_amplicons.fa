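>L1rep
CAAGTGACACGATATTTACGTAAGTAACCCCCTTAGCTTACCCCATCCCAAAATTTGGAG
>GAPDH
CAGGAACCTGAGGTGCACTTTGGAAGGACTCAAACGGACAGATGAGCGCCTTAGCCGGGG
>PABPC4
CATCCCACTATATCGCTCCGTGTATATCGAGTCATTCGTTGGACTACGCATCTCCATGCG
>L1_3end
GGCAAGATAGCGCAAGGTGAGACTTGTGCGCGTGCATGATTTGCTAGCTGCCCCTTGCAG
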