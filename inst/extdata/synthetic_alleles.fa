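>SYN:00001 L1*01:01 300 bp
TATCCAGCCCTCTATTGTACTCCTATCTCAGCGCCTATGCCACTTCGACTGCGCGGTTAG
GAGCAATAAGATGTGCGTGGGCGCATGGGAGGCGCTGGCCATATTGTATGGAGGTAATCG
TAAGGTCGCGGTTGGAGGTCCGCCACACAACTACTCTTTTAAACGGCTAGACGAGTACGG
ACAGACCACTTTGCGTGACTCGCGGAGTCTAGTCGATCTCAGGCACACAAATAAAACTGT
GGCCTCTTCCCGCGGCCTGTATAGGTAGCTTACGCTTCACCAGACCCTTCCCTCTCTGAT
>SYN:00002 L1*01:02 300 bp
TATCCAGACCTCTATTGTACTCCTATCTCAGCGCCTATGCCACTTCGACTGCGCGTTTAG
GAGCAATAAGATGTGCGTGGCCGCATGGGAGGCGCTGGCCATATTGTATGGAGGTAATCG
TAAGGTCGCGGTTGGAGGTCCGCCACACAACTACTCTTTTAAACGGATAGACTAATACGG
ACAGGCCACTTTGCGTGACTCGCGGAGTCTAGTCGATCTCAGGCACACAAATAAAACTGT
GGCCTCTTCCCGCGGCCTGTATAGGTAGCTTACGCTTCACCAGACCCTTCCCTCTCTCAT
>SYN:00003 L1*02:01 300 bp
TATCCAGCGCTCTATTGTACTCCTATCTCTGCGCCTATGCCACATCGACTGCGCGGTTAG
GAGCAATAAGATGTGCGTGGGCGCATGGGAGGCGCTGGCCATACTGTATGGAGGTAATCG
TAAGGTCCCGGTTGGAGATCCGCCACACAACTAATCTGTTAAACGGCTAGACGAGTACGG
ACAGACCACTTTACGTGACTAGCGGAGTCTCGTCGATCTCAGGTACACAAATAAAACTGT
GGACTCTTCCTGCGGCGTGTATAGGTAGCTTACGCTTCACCAGACCCTTCCCTCTCTGAT
>SYN:00004 L1*02:02 300 bp
TATCCAGCGCTCTATTGTACTCCTATCTCTACACCTATGCCACATCGACTGCGCGGTTAG
GAGCAATAAGATGTGCGCGGGCGCAGGGGAGGCGCTGGCCATACTGTATGGAGGTAATCG
TAAGGTCCCGGTTGGAGATCCGCCACACAACTGATCTGTTAAACGGATAGACGAATACGG
ACAGACCACTTTACGTGACTAGCGGAGTCTCGTCGATCTCAGGTACACAAATAAAACTGT
GGACTCTTCCTGCGGCGTGTATAGGTAGCTTACGCCTCACCAGACCCTTCCCTCTCTGAT
>SYN:00005 L2*01:01 300 bp
GAACGTCCGAAGTCGCCATTACGGCGATACGCTTTTTAGGGCATTGTTCGCCCAACTGGT
GGAACAAGCTGTACATTTGGATTATCGACTCAGCTTGTTACCGATCACTGTAGCCTTCGA
AAGGTCCGCCGCACGTGATGGCAAGCCAATCACTACCGACTTTCCATTCCGCCCACAGGA
AGGGATAGGTTTAAGCGTGGACACCCATAGACGTGGGTCTCAGATGCAAGACAGGTTGGC
ACGAACCCCCAAGTTCCTCCGCGGATGGAGGAGATGTGACAGAGTGACCTTCGCGTTACT
>SYN:00006 L2*01:02 300 bp
GAACGTCCGAAGTCGCCATTACGGCGATACGCTTTTTAAGGCATGGTTCGCCCAACTGGT
GGAACAAGCTGTACATTTGGATTATCGACTCAGCTTGTTACCGATCACCGTAGCCTTCGA
AAGGTCCGCCGCACGTGATGGCAAGCCAATCACTACCGAATTTCCATTCCGCCCACAGGA
AGGGATAGGTTTAAGCGTGGAGACCCATAGACGGGGGTCTCAGATGCAAGACAGGTTGGC
ACGAACCTCAAAGTTCCTCCGCGGATGGAGGAGATGTGACAGAGTGACCTTCGCGTTACT
>SYN:00007 L2*02:01 300 bp
GAACGTCCGAAGTCGCCATTACGGCGAGCCGCTTTTTAGGGCATTGTTCGCCCAACTGGT
GGAACAAGCTGTACATTTGGATTAACGACTCAGCTTTTTACCGATCGCTGTAGCCTTCCA
AAGGTCCGCCGCACGTGGTGGCAAGCCAATCACTACCGACTTTCCACTCCGCCCACAGGA
AGGGATAAGTATAAGCGTGGACACCCATAGACGTGGGTCTCAGATGCGAGACAGGATGGC
ACGAACCCCCAAGTTCCTCCGCGGTTGGAGGAGATATGCCAGAGTGACCTTCGCGTTACT
>SYN:00008 L2*02:02 300 bp
GAACGTCCGAAGTCGCCATTACGGCGAGCCGCTTTTTAGGGCATTGTTCGCCCAACTGTT
GGAACAAGCTGTCCATTTGGATTAACGACTCAGCTTTTTACCCAACGCTGGAGCCTTCCA
AAGGTCCGCCGCACGTGGTGGCAAGCCAATCACTACCGACTTTCCACTCCGCCCACAGGA
AGGGATAAGTATAAGCGTGGACACCCACAGGCGTGGGTCTCAGATGCGAGACAGGATGGC
ACGAACCCCCAAGTTCCTCCGCGGTTGGAGGAGAGATGCCAGAGTGACCTTCGCGTTACT
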