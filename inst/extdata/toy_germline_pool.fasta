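>IGHV1-S1*01
ACATCTGGAAAGTGTATGTGGGAATACGGCCACGATGGTTACTCTACCAACCGTGTCCTCAGGTGGTTTATGGCGTATCTACTCTTCCTATACAATCATGCAGGTGGCGATTCTCGTGACGACAAGAGGGGTGGGAGCGGGACTCGAGTGGGTTGGCTGCTTCGGATAATCCTAAAGTCTCTTTTTGAACGAGCCCAGCCTATGCAGCCGAGCAAAACGCCGTCGGCGACTGTGACCGCATATTTATGTAACGTCCATTTTACCCCGGTGGTGGTAGGCTATACACCGATCCGCGGATGT
>IGHV1-S2*01
GCCCGCGTTCAGGACGTGACCCTGTCTGGGCCCAGCATTCTGACAGACTTCGGCAGTCTTAGACAGTTGTTAGGCCTTATCCATGACTCCCAGGCCATAAGACTTTCACCCGCCGTATACCAGACGAATGTTCAGGTCGCGGGTCATATCCGCGACACCATCTGTAGTAGAGAGTTTCATGCGATCTGGCAGATCACTATCAACCAAAAAGCATTGACGGCTTCAAACTTGGTGTGGGGGCCGGACTGCCAGAGCTGGAGGTCCGCTCGCCGTACCTTTAAATTACGCATGTGCACATGT
>IGHV1-S3*01
TCCAATGATCTACATACACTTGTAGCGTTATACTTTCGGGCACAAACGGCGCCGTCTTATTGCCACAGAACGAAAATTGCTGCAAGTTACTACCTATGCCAATCAACACCTTTTAAACCTACTGAATCAGGAGGCGCAGCACCATACTTCTCGATTGTACTCGTCGGACGCGAGCATTGCGTCCGTGTGTTTCTGCACGCGGACGACGCTGTGTATCTAAGCGTGGGGACCGGACCACCAAATAATTCCGAACAGGAGACTAAGTTTGCACGTGTATCCGTACGTTACGATTTCTGGTGT
>IGHV1-S4*01
GCGTTGTGGTCCTCTATTTACTATGCAATGGGGCGGCTGACCCAATTGACGTATAAACGTGTTATAAGCGGCTATAAGTTCCTTGTCTTTGCGACTAAAAGGGGATTCCACCCAGACCTCGTATACTTCAGTATAACCCTAGTGATTCCCCTGTCTGACATGATAGCGAAAATCAAGTTTGTCCATCCGTATGGACGACGGAGGGTACCCTCGTTTTATATGATCAGAGAGTGTTCGACAGAGAGGATACTCCCCATCGTACCAATATACATGGACGGTGTTAAGATGAATAAACGTTGT
>IGHV1-S5*01
GCGGAACGTTATTTCAGAAATTCGAAGTTTGGACATGATGCGTCTTCAGTGTCAATCGAGGTGATGGTTGTGAGGGCACGACATCGGCATAGTTTTCTGAATACTTCCGTCCGAGCATGCCATATTTGCAACAGCCCACGTCGGTTTCATAGCAAGCCGAATCCTGCGCTTTGGCGGGAAAAACTGGTAACGGGATCATCTCGACCCTATGAATCAGAGAAACATTATCGGCCAATGGCGGGGAACGGAGCCGGGAGTTCCTGGGCGGTTTATGTGATTGCGGCCCTATTATATCGGTGT
>IGHV1-S6*01
GCACCTAGTTCGGCGGCGAGAACTCTTAAAGGCAAATTAATGCGTCCGGGTCGGGTCAAAGGGCAAGTCGCAGCCGTTCGGGTATCAATCCAGCACAGCATTCTATCAGCCAAGGCCACGCAAATGGCGTTGCAGTCTGCGGATCGCGGATTAGTCACTGGTGTAAATTCGGAGTGGTACGCTAATCGAACCCAACGTCGATCCAACAAAACACTTTGCGGTTCCGTAATATTGGCCGTAAGGAGACTCCTTGAAAGCATGCATAAAACTAAGGTTAAACCGGTAAATTACGTCCCTTGT
>IGHV1-S7*01
TTTCCATGGGCGACACACGAGTTCCGTGTTGCCTATCTTCGACTCAATTTCAGTACAAAGACGAAGCATACTAGATTACGGCTTGTTATATGCGCGATGGCTTTATGGACGCAACCCACTTCTAAGATTAGTGGATCTGGAGGCTTCTCCTATGTTCATACTGGTATGGTCCACGGAGCTCAAATTCTAACAAGTAGGGTGTGGAGTGTTGCTAATAGAAACGGTCGTGTTCCCGCAAGACCGATAAAGACAGTGTCAAAGCGAAGACTGTCTCAGCTTTCGAGATCCCGGACAGCGTGT
>IGHV1-S8*01
GAATACCTGACTGGTCATCGGCACTCGTATGTTAACCGCTTATTACCTCCCCAGGCACGATATGCCTGTCAAGGTTCGGGTGACTCTGCGCACGGAGACTCCGATGACAGAAAACGGACACACGTAGGCTCCTTCTTTAGCAATCTATCACTTCTAACAGGCAACATATGGTATAAAGGTCTTAGATACAGCGTTAGTTATATGCCGTTACGACTTGCTCAAAGCGCTACATTAAAGAAGGTGAAGAAACACTGCAACACCGGCCGAATACACGACAGTGACGTAGTCGTGTTTCCATGT
>IGHV1-S9*01
GACGGCATCACATTTGATCCCAGGGTTAAAACCCGGGTGTGCTCACGAAGAAAGAACTTACAACGTATCGGCGGGATTAACAATGCTGTCTTTTTGTCCCTAATGGCGATCCCTCAGTCCCCAGGCATCGTGACTTTCGCGGGTGCCTATTTTTTCATTCGCCATCTTCAAGACGTTACTGTTGCCTGCCGAGCTTCAGGTCTAGGGTATAGCGTGTCTCCCCTTGTTACTGGGAATGTAATTACAATTGGTAAATTTGCGTTGTCGTCCCCTCCGGAGAAGAGCGCACCGCCATCATGT
>IGHV1-S10*01
TTAAGGTGGCCACTTGTATCCTGGGAGAGGCTACCCGGCCGAAGATCGGTTGGCGCCTACGAATGGTTCGAGTCTGGGGTTGAAGGGGAATGTTTTCCGCCCCCCAGAGGATTCTTGTGGCGCTATTGCAATCAACTGATACCTTCCTTCAAGTGTTGTGCTCATGAAATCGATGTTTGTATCCTTCAAGTGGTAGATCATCGGAGCTTGCTAGTTTTTTCGGTTCGCTCAGTCATATCTTACTATTTTCAGTCTCCACAAGATCTAGGACTCCAGGTTCAAGGGCCCAGATTACGGTGT
>IGHV1-S11*01
ACCGGAATAAAAAACCCCTCACAGGTCCCGCGTGACGTCTGTAGCATCGCCTATGGCCAGTCCATTTCGTATTGCGGGGGAGATACGCTGGACGTAGGCCAGTGGCGATATCCTCGGTTAGACTGCGGCAGTTTTTTTGGAATCCGCCTCATCAGTAGGTCATGGCTATATCTGTCCGTCGTTTCTATCTCCCGAATCTACCGCAGTAGGGAATCATTAGTGCGTTTGGAGGCCGAACTGATACTTCGTGGGAGATGCTTGCACAAGTGCTTTGGAGGACTTCCATCGATAAGAGTTTGT
>IGHV1-S12*01
AATTTGAGGGTCAAGAGGTGTACGTGGTGCTTCTATTTATTTCTCAAGGAGATTTTTTATGTGATAACGCTCAGGACTCGAACGTGGCGCCGGAGGTACGTTGGGCTCGCATTTGTCTCTTGTAACGAATTGAATTACGCGGTGGGCACCACATCTGTCGTCATCATCGGGATAGAGGGCACTTCATGGTCAAAAGCTGGATTCGATAGAGTAATGTGGCTCGTTGCACATTTATCATTCAGGTATGGTCCCTCTGTACCGGCAAAGGAACAGGATGGGGGCCAGATCGTTAGTCACTGT
>IGHD1-S1*01
TCCCTCACTAATCGACGCTTA
>IGHD1-S2*01
GCGTCCCGCGAAGGGAATAAGAAT
>IGHD1-S3*01
GGACCCCTGACACCACTGGACGTCATT
>IGHD1-S4*01
AGCGATAGTGCGAGGCATCATTTACACTCC
>IGHD1-S5*01
ATGGGACGGTTTATTCCGCCAAGT
>IGHD1-S6*01
ACTACTGTGCTCAGGTATGCTCGAATC
>IGHJ1*01
TGGCTAATTCCTGGCGGATTGAAGTGTTGTGCGTCGCATACTCGGAAA
>IGHJ2*01
TGGAGAGGTCCAGATGGGGAAGGGTCGACGAGTCATGCCGGCAGAGCT
>IGHJ3*01
TGGCAAGGACCCAAAGATAGCGGGGAGTTAGTAATGTTTCAGGCCTCT
>IGHJ4*01
TGGCCCAGACGTTTTAGGGTGAATGCGTTTGCAAGAGAACGATACCTG
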