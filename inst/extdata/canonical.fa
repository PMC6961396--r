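>chr1
CGGTCACACCAGGAGAAACTCGTAAAACTTCAAACATCACGTATGATTACAACTCCCATGAAAAGCCACC
CCTCGCGACCTCATGAGGAGTTGGGGCTTAAATGGAGTCTATGCGAAAGCGCGCCTTATATGGGTATACG
AATGAGGGCGACCATCGGGACTGTTGTTAACTGATACAAAATTTACTCCACTTTACTGACGGTTGACCCG
CTGCTGCTTTAACCTCGACATGACGAAAGCCCGATACCTTTGCTAATATTTTTAACATGTAAGGTTTCAC
CGACAGTACACTGCAGTCATGTGCGCCAAGAGTCCTGTGCTGAGAATAGGTATTAGTCAGTCGATTAGAC
TGTCACGTTCTATCTAGTCGTAAACGTTTTGCGTAGCCGAGTTTATATCAAAGCCTTGACAATCAGAAGC
TGGTTGACTGGCGCTCTCGCCACTACGGGCTTACGGGAGCCAACAATTGACCAGATCTTCTACCACTTAT
ATATTTATATTCAGCGTGGCAATCTTTCCAAGGCGTTCGGTAGACGGCTTTGGAAGTCTCTCAGGTCCCG
TGATCTGATCGCCGTTCAAGCTAAGGAAAGTAGATTGTTA
>chr2
ACTTTGAGTATTCCCGCTCTGTGGTGGGACGTTACACATCGTAAATCCCGATGCTAGGGGATCCTACCGT
GTGCGCGGGAATATGATCAATGTCGTAGCTCCGGAATTAGCGGTGACCAGCTTCACTAAGCCGGATGGAT
CCTCTGCGGACTAATCAGAAACTACATGGTCAGCGCAACCCGTTTATCGGATTACAGATGGCTCCCTGAA
GCAGCATTCTCGGGCTTGGGGCTAAAGGACTGCCGGATCGCAAATATCTCGCCCAAACCTGGGTAGCGGG
AAGTGGAGGAGGTGGCAGTGGCTCCTAACCGGGGTTATGGCCAGACAGTCATCAGTAGGACGTGAGGTCA
GGTCTACCTCTGGTCTAACTGTTAGGTTGGCGCAAGTAGCATAGACTTTGTTACTCTTTAGGCGTACGAT
CAAGCGATAGACTTTCCATGTCATCCGACT
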