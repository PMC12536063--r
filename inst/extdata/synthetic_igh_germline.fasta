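>IGHV1-2*04
AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGACC
CCCTGCACGCCCAGTACAATTAGGATATTCATCCCTACACTGTATATGCCGAACGTTCTA
ATAAACGACTTAGCAACAAGTCGCCTAGAAAGGTACCGCTGGCATATCACGCCTCCCGCT
TGCCGTCTTCAACTTCATGACCCTCGTGCATCACAAAGCCTCAAGCCGGAGTCTAGGCTT
AACAGCATAAATCGTGTGAATACGGTCGTCGGAAAGCAGTTGAATTGTGCG
>IGHV1-69*09
ATCCGACCCCTGCGCAAGGACACACTAGTCGCCCTTGAGAGCACTCCAGTCCAGGCGAGG
TATCCACGACGATACGACTCGGCTAGCAAACGCGCGGTTTATCTATGCAGCTATCCTTCG
ACCCCTGAGATGACCGGTCATCAGGCGGCATCCGACGCACCAACGGCTCCTACAGACTCG
TGCTACCGGACCATGCGACTCGAACATCAGATGGACAGACCTCGTAATAGCCGGGCCATG
CACTGTCTCCGGGCAGCTCATGACGAGCACCAGACCCGAGAGTTCTGTGCG
>IGHV1-69D*01
CTGTTAGTTTTGGTTAGGCACGGAACGCTATCGAGCGCGGCGCCAACCCGCATTTACGAA
GTACCCATCGTATGTAATAAGACCTCGAGTACGTCGGGACGTTGGCTGTGTTTTGATGAG
CGAAGTTCGACGTTGCCGATGTTTACCCTAAGGGAGACGACATCATCGCACGACTCGTCA
TTTGCATCATCTCCACTGCCCCGATGTCTGCTATGGACGGCTTCACCTGATGTGGAGCGA
GGGTACATATACGACAATGCACGTAGTCTCGATACGTCATTGGTATGTGCG
>IGHV3-7*04
CGAACAGTTCGTATTCCCCATGTCTGGACCGACGTTAAGCTCATGTCTCAGGACGGAGAA
TGCAGCCCAACAGCTTGGCCGGATCAAGCAGGAGAGGCACTTACTTTCCCCGCTACGATG
CTTTGCACAAATTCTACCGCATTGATCGTGGATTACTTTTGGCATGGGTGGTGGAGCCAA
ACATCCAGCCAGCTGCAAGCTTTGCCTACGTGGAGTCTCTGTGAAATTCAGAGATACGCA
GCTAATGGCCCCGCTCGGGTGCATCGGCACAGCCTCGTGCAGCCCTGTGCG
>IGHV3-11*06
TCACAAATTTCCGCCATCAGTGATTCAGTATTGTTTCACCGCAGTTACCGTGAAGTGCCG
CCATATACACAGGTTCATGCTAGAGAAACTGCCACCCGGGCTTGCCAACCGGCAACGTGG
CGTTTGACAGAGCTTCTTAAGCCGCTGATGTCCAAAAACGTTAGTTCGAGATTGGATGTC
GCACTAGAGGGAACAGCCATAGGACCGATACAGACAGTTCAATGGCGGATGCCCGCACCT
GTATACACCTATGTAAAAATTGAATACGAGAGGGGCACCCTTTTGTGTGCG
>IGHV4-34*01
CCCTCCCACTGTCTATTCCAGGTCGCCGAATATGTCCCGACTTCGACCCGTTTGGTAGGC
CAGGGGCCTGGGCTAAACACGGCCTTCCCGATTGCCATGAACTCGTTTCGCCTTAAAGTC
CAACCGAGAAGCGACAGCGACCTAATCCGAGCTTTATCTTTTAAGCGGGCGCGGGGATGG
AGTCTAAGGCACAGACGGATGCTCATCATATCTCGTAGCATTCATAATGTTGTGAAAAAC
GGAGCTGGGTCAACAGATATGGGTAGAATTACCGGCAGCTCTTTTTGTGCG
>IGHV5-10-1*03
GCCGGTGGGTGCCCGGCGACCCGAAACTCGGATATGCATGGGGGAGGGCCACCCATTTAT
GTGCGAGCTGGAAGACGGTTCAGCGGTCCCTCTTTGGATCGATTCCAAATGACTAACTAC
GAGACGGGCGTAAAACTTAGCGCCGTAGCAGAGGAATCAGGAGAGGCTGGTAAAACTAAG
TGTGAAGTAAATGCGGCGCAGTTTGGTAGACTCATAGTAGACGCATACTCTGAAGTTCGA
AGCGGTTCCTTTTTGCTAATTAACCAACAAGCCACGAGAGTTGTCTGTGCG
>IGHV6-1*01
CTCGTGTTTCGCAGGGTAAATGGACATTTGCGGCCGCCGCTCATGCTCGATATGAATAAG
TTCAGTGGGATACCATCGATCAGGGAATCCCTAGGCCAGCGGATATCACAATCCCTGTGG
CACGGCATGGTGGGCTCCCCTTATCTTAGGTTTAGTAGCACGCTGATCCGCTCGATGAGC
AAAAGACCGACGCAGTCCGCGCTTCATGCAGCTAAGTTATTATTAATCTTTCTCCAGGTT
GGCTACGCTACCGTTCGGCAAACATATAAGATACTATTAGGTGGCTGTGCG
>IGHJ4*02
ACTGCTAGTGGCCGATGGGGCCTGGGAACCCTGGTCACCGTCTCCTCA
>IGHJ6*02
CTAAGTATTCCCGTTTCATGGGGCGTAGGAACCCTGGTCACCGTCTCCTCA
>IGHJ5*02
TACCACGTGAATCCACCAGGGTGGGGCAAAGGAACCCTGGTCACCGTCTCCTCA
>IGHJ1*01
ACCTTAGTAGCGGCCCGGTATAGCTGGGGCCAGGGAACCCTGGTCACCGTCTCCTCA
>IGHD3-10*01
ATAGGGTAGTAAGGGAGGCCATCAACGAT
>IGHD2-2*01
GTGCGGTGTGGAATCCCAGAGAGGG
>IGHD6-19*01
AGGAGGCTAAAGCTGTTGA
>IGHD1-26*01
GGTAGGACTGACAGTGTGAGCGCGAA
>IGHD3-22*01
GTCGTGTCTTCGTTAGGCTGACGCACTATA
>IGHD5-12*01
CACGTCATACGCTATCATGAA
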