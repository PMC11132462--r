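LOCUS       pGb1              456 bp    DNA     circular SYN 01-JAN-2020
DEFINITION  example record.
ORIGIN
        1 gcgcatgggaggcgctggccatattgtatggaggtaatcgtaaggtcgcggttggaggtc
       61 cgccacacaactactcttttaaacggctagacgagtacggacagaccactttgcgtgact
      121 cgcggagtctagtcgatctcaggcacacaaacgcttcaccagacccttccctctctgatc
      181 ccagctaagatatccagccctctattgtactcctatctcagcgcctatgccacttcgact
      241 gcgcggttaggagcaataagatgtgcgtggatgccagctgtctctgagcgattcgggcgg
      301 gggaacatatccattgatttccccggtagtgcatacaagacgcggttaactcgcaacggt
      361 gtcgttgtacatccgcagttgcgtttagctgtgtaattgccacaggaccgagcacctata
      421 tgggcacgtcatcagagtaatccaagacctgcgggg
//
LOCUS       pGb2              300 bp    DNA     linear SYN 01-JAN-2020
DEFINITION  example record.
ORIGIN
        1 gcgcatgggaggcgctggccatattgtatggaggtaatcgtaaggtcgcggttggaggtc
       61 cgccacacaactactcttttaaacggctagacgagtacggacagaccactttgcgtgact
      121 cgcggagtctagtcgatctcaggcacacaaacgagaggcagcacatagaacgtccgaagt
      181 cgccatatccagccctctattgtactcctatctcagcgcctatgacacttcgactgcgcg
      241 gttaggagcaataagatgtgcgtggatgccagctgtctctgagcgattcgggcgggggaa
//
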