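>synthetic_clone_TRF1_standin Ba27f/HhaI T-RF = 95 bases (synthetic stand-in, not a deposited sequence)
AGAGTTTGATCCTGGCTCAGGGTTCCCCGCCCCAGGACGTTGCCTTTTACATTTCAAATTCGCAAACATC
ACTAGGCTTTCGTAGGGCGGTTGCGCTCCAGCGGGCCATGTTTGGAACGGGGTCGCGATGGATTTATCGA
GGGTCGTGCGCTCGCTACAGACCAACCCCAGGTAAGTCGTTCCGCTGAGTCCCACCGTGTAGATTTGCGG
AGTAAGGAGCGACCAATTGCTACTGAAAGAAACGGTCCCTGAGGTGATTCGAATATAGTAGTCAGTGGAC
GCAGCTTGCTCGAGTCTTTCTGGGGATGTTTCCTCCCGTGTTTGTGCTGGCCGCGCGATATCGCATTAAT
GGCTGTCCCACACGGAGACACTAGCATATACCCGGTTCAATGGTTGATCTCCGACTCCCGTACTGCGAGG
CCTAGTAAGGCTGCCAACCCAGCATCCGGCGGTGTATAGAACACTCTCCAGCCGTTCCTACGGCTCAACT
TACAGGAGTGGAAGCGATGAGTGGATTCGCGGTTACTAAGCCACCCGGACAACCCACAGTCAGGCACACG
TAAGGGTCGCCAGGAAGTGTCCCACGGTGTTACAAGAAGCGGGGTCCGGCTACCGCAAACGAATCTTATA
AGCGTGGATCAATGGGGTTCCCAGTTCAAGAGGCCATCGTTCGTGACCTGACGTCGTATCCCACTGGAGA
TGTTTTGGCGATGGTAGCAAACGTAGGGTACTACACAATTGGGAGGCCTCTTGACGATTCCACAAAGTAA
TAGTTACAGGAGCCGCACAGTTTGAGGTGCTCCCAACTAGGTCTCGCACCGAGAGACAGACCTCCAGTTG
GTAGCCGTGGATGGGCCGACTCCGTTACACAGTGGCCGGGCGGTCAGAGGAGGGCACGTG
>synthetic_clone_TRF2_standin Ba27f/HhaI T-RF = 284 bases (synthetic stand-in, not a deposited sequence)
AGAGTTTGATCCTGGCTCAGCCCAACTAATATGATACTATCACCTCCAACACTTAAGCGACTATATCCTA
GGGCTGAAACCCGCGTGGGGTGACCGATGTGGCTGATCACGATCGAGGGGTTCTGACTGGCGAAGGTGCT
ATCCACTGTGACCTCGATGTCACACAAGGTGGGCATTTTCCTCATCTGTGTCCTATTCCCACTCGACGGT
AATATTTACGAGGGCGTCTTTACGATATGTCTATAGCTCACTTTAGTCAGGGAAGTGAGGCGTGACCTAG
AGCGCAAAGTATTGCTCGTCAAACTGCCTGAAATCCTCCCTCCTTGCGGGCCAGTAACATATCGACTTGC
TACCTTCTTTGCAGCGCCGCTTCCGTTTCGAAGTGCTGAAGCATCGCGTGGGGCTTGGCATTCGTTATGC
ATATCTACGCCTCCTCGCCAAATGGCGCGTCTAAGACTCTCTCCAAGTTGGGCGCCGTCTGGACAGGAAC
AGGCCTGGCTTAACACCATACGGAAGGAGGGCACAGCATAGAGACTGGGCGGGAGGGAGAGTCTTCCCAG
CAACGTATATAGTTTTGATATACCACTTCAATCACGTCGTTAAGTAGGTTGCCGCTTAGTAATATGATAT
AAACGCGGGTCTGTACAATGGCACTTTGGCGTCCCCCGCATTTAGGTAACAACAACGCAACTAGGGCCCG
AATTATACGTAGAAGGGTTGCCTCCCAGAATGTTTTGCCCCGTGGCGTCTGATGTGACCCCTCTACATGG
TATCGGGGGTCAAGACGAGCGTAGCGCCGTATACGACAACGGTGGCCATCATGGAACTCAGCTCGGGAGT
TTTAGCGGGCCCTGTCATCGAACAGATGACTGCGATTGCGACCGGGTTCGAGTATAGTTT
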