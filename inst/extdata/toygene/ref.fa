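>chrT
AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTGCA
CGCCCTAAAGTACAATTAGGATATTCATCCCTACACTGTATATGCCGAACGTTCTAATAAACGACTTAGC
AACAAGTCGCCTAGAAAGGTACCGCTGGCATATCACGCCTCCCGCTTGCCGTCTTCAACTTCATGACCCT
CGTGCATCACAAAGCCTCAAGCCGGAGTCTAGGCTTTGAAACAGCTGAATAAATCGTGTGAATACGTGAG
TCGTCGGAAAGCAGTTGAATATCTAACGACCCCTGCGCAAGGACACACTAGTCGCCCTTGAGAGCACTCC
AGTCCAGGCGAGGTATCCACGACGATACGACTCGGCTAGCAAACGCGCGGTTTATCTATGCAGCTAATAT
CCTTAGTAGTCGACCCCTGAGATGACCGGTCATCAGGCGGCATCCGACGCACCAACGGCTCCTACAGACT
CGTGCTACCGGACCATGCGACTCGAACATCAGATGGACAGACCTCGTAATAGCCGGGCCATGTAACACTG
ATGTCTCCGGGCAGCTCATGACGAGCACCAGACCCGAGAGTTCCTGTTAGTTTTGGTTAGGCACGGAACG
CTATCGAGCGCGTAAGCGCCAACCCGCATTTACGAAGTACCCATCGTATGTAATAAGACCTCGAGTACGT
CGGGACGTTGGCTGTGATGTTTTGATGAGCGAAGTTCGACGTTGCCGATGTTTACCCTAAGGGAGACGAC
ATCATCGCACGACTCGTCATTTGCATCATCTCCACTGCCCCGATGTCTGCTATGGACGGCTTCACCTGAT
GTGGAGCGAGGGTACTGATAGATATACGACAATGCACGTAGTCTCGATACGTCATTGGTACGAACAGTTC
GTATTCCCCATGTCTGGACCGACGTTAAGCTCATGTCTCAGGACGGAGAATGCAGCCCAACAGCTTGGCC
GGATCAAGCAGGATGAGAGGCACTTACTTTCCCCGCTACGATGCTTTGCACAAATTCTACCGCATTGATC
GTGGATTACTAGTTTTGATGGCATGGGTAATGGTGGAGCCAAACATCCAGCTAGCAGCTGCAAGCTTTGC
CTACGTGGAGTCTCTGTGAAATTCAGAGATACGCAGCTAATGGCCCCGCTTAACGGGTGCATCGGCACAG
CCTCGTGCAG
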