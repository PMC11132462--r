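>pEx1
GCGCATGGGAGGCGCTGGCCATATTGTATGGAGGTAATCGTAAGGTCGCGGTTGGAGGTCCGCCACACAACTACTCTTTT
AAACGGCTAGACGAGTACGGACAGACCACTTTGCGTGACTCGCGGAGTCTAGTCGATCTCAGGCACACAAACGCTTCACC
AGACCCTTCCCTCTCTGATCCCAGCTAAGATATCCAGCCCTCTATTGTACTCCTATCTCAGCGCCTATGCCACTTCGACT
GCGCGGTTAGGAGCAATAAGATGTGCGTGGATGCCAGCTGTCTCTGAGCGATTCGGGCGGGGGAACATATCCATTGATTT
CCCCGGTAGTGCATACAAGACGCGGTTAACTCGCAACGGTGTCGTTGTACATCCGCAGTTGCGTTTAGCTGTGTAATTGC
CACAGGACCGAGCACCTATATGGGCACGTCATCAGAGTAATCCAAGACCTGCGGGG
>pEx2
GCGCATGGGAGGCGCTGGCCATATTGTATGGAGGTAATCGTAAGGTCGCGGTTGGAGGTCCGCCACACAACTACTCTTTT
AAACGGCTAGACGAGTACGGACAGACCACTTTGCGTGACTCGCGGAGTCTAGTCGATCTCAGGCACACAAACGAGAGGCA
GCACATAGAACGTCCGAAGTCGCCATATCCAGCCCTCTATTGTACTCCTATCTCAGCGCCTATGACACTTCGACTGCGCG
GTTAGGAGCAATAAGATGTGCGTGGATGCCAGCTGTCTCTGAGCGATTCGGGCGGGGGAACATATCCATTGATTTCCCCG
GTAGTGCATACAAGACGCGGTTAACTCGCAACGGTGTCGTTGTACATCCGCAGTTGCGTTTAGCTGTGTAATTACGGCGA
TACGCTTTTTAGGGCATTGTTCGCCCAACTGGTGGAACAAG
>pEx3
GCGCATGGGAGGCGCTGGCCATATTGTATGGAGGTAATCGTAAGGTCGCGGTTGGAGGTCCGCCACACAACTACCCTTTT
AAACGGCTAGACGAGTACGGACAGACCACTTTGCGTGACTCGCGGAGTCTAGTCGATCTCAGGCACACAACTGTACATTT
GGATTATCGACTCAGCTTGTTACCGATCACTGTAGTATCCAGCCCTCTATTGTACTCCTATCTCAGCGCCTATGCCACTT
CGACTGCGCGGTTAGGAGCAATAAGATGTGCGTGGATGCCAGCTGTCTCTGAGCGATTCGGGCGGGGGAACATATCCATT
GATTTCCCCGGTAGTGCATACAAGACGCGGTTAACTCGCAACGGTGTCGTTGTACATCCGCAGTTGCGTTTAGCTGTGTA
ACCTTCGAAAGGTCCGCCGCACGTGATGGCAAGCCAATCACTACCGACTTTCCATT
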