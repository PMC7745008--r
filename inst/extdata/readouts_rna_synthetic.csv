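readout_id,sequence
R01,GCATTGATCTGGGAGGCGAT
R02,TTTATACGGCCGTTTGATAG
R03,GTGGGTTGACTAGACGGCTT
R04,CACTCTATGACGCACCAGTG
R05,AGGGGTTCGCTAACAAGGGC
R06,CACCCATAATTTACCGCCGG
R07,CTCGATTTCCTCCCTCCGCT
R08,CACAGCTGTAAACCAGCCGC
R09,ATCCTCCCCGATCTCTATGT
R10,CCCCATAGCTATATCGAGCT
R11,GATTCTTCTGGTAGGGCATG
R12,ATATTAAGTCGGGAGAGGAA
R13,TGTGGATGAGTAGCTACTGC
R14,CGGCACGAAAGAATTGCAGA
R15,CCAGATATCAGTTGACCCCG
R16,AACTCCGCTCGTAAAGAAGT
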