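readout_id,sequence
DR01,AACGGACGATGCGTGTATGG
DR02,CTGTGAGACTAAGCTCTACT
DR03,CGAAACATCTTTCGTGCCAC
DR04,CTCATATCGCATCCCCACAC
DR05,CACGAGGACCGTAGTTTCCT
DR06,TGTTCCGAAATAACGACTCG
DR07,CATACACAGCGGCTTTCGTT
DR08,GAGGGCTTGATAAGGGTGGT
DR09,CGAAGTGATTGGTACAACTT
DR10,AAGAAGACCCATCTACAGTT
DR11,CTCAGCAACGCAGGAGGATC
DR12,GTCGGTCTTACCTGGTGAAG
DR13,ACGATCTTTATCCCTGGAGA
DR14,TAAGTTGGGAGGTGCCACCA
DR15,ATAGCAGGGGCTTGGCGAGT
DR16,GAGCTGTGAGTGACCGACGA
DR17,GTGTGTCGATCTGCTTCTAC
DR18,AATCTACGCTTGGTGGCTAC
DR19,CGCACTCAAGGTGTAATCCC
DR20,CGACCAATCTAAGGAACGGC
DR21,CGTGAAAGGATCTCTGACTA
DR22,TCACAACCGTGAATGTCAGA
DR23,TGGATCTAGATGGCTCTTGT
DR24,GAGGAAATAGTATCAGGCCG
DR25,ACAGCGAGCAGCGTTTTAGG
DR26,AAGTACGGAGAGTCTGCAAA
DR27,TCAGAAGAGCGCGACTCCAC
DR28,ACTTACACCTAGCGCCATAC
DR29,TCGAAGTTGGGTCCCTGTAA
DR30,TATGGGGTAAGGCTTTAGGC
DR31,CATTGAGAAATAAGCGTGGG
DR32,TACATCCCTTGCTTGAGCTA
DR33,GATTGTACTCAGAACGGGCG
DR34,GTGGCCAATCGGTGGACTAG
DR35,TCGACTGCGTTCTCTTATAG
DR36,TCGTTCGTTGTCATACTTCA
DR37,GCGGCAGAATCGCGTTTAAT
DR38,ACAGCTGAACGCCGTCGAAA
DR39,TCTCAAACTTGCAGCTGTCA
DR40,CGTAGGAACTAGCGGGATTA
DR41,TGCTGCTGTGATTTTGGACG
DR42,TTTGCCTCCTCCTAGTGGGT
DR43,ACTGGTCCATGTTCTTTCCC
DR44,AGCGGATATGCGCCCATCAA
DR45,TCAATCGGGCAGCAGTCAGG
DR46,GGCAAGCGAGTACCGTGATC
DR47,TCTCCTATCCTGCGGCGATA
DR48,CGGCTCGTCCACATTTAGCC
DR49,AACCGCTGTCTGGATTTAAA
DR50,GTAAGACTTAGGCTACTCTA
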