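>synthetic_clcn2_wt_cds
ATGAGCACCTTGCAATATGGCCGTTGTCCATACCGTCACCCACAGGTACGGGTACCAGGT
TTTAACATTTCGGTGCCCGTAGAGACGTATGTCGGTTCTTATGACTTAGATTCTAATGAT
CAGCGTGATGCATGGGCTTACGAATCATATAGTGGTCGGCTCATACGGCAGCGGAATCTG
ACAATAACGATAAGCCTTGACGTTAGCAAGGCTACTACTAAAATATTTCAGCGAAACCTG
ATGGATGTTGAGAATAGTCTGCTCCACGGCAAGCTAATGCCCGAGGCGTCCGCGCCTCCT
GCTGGGTACATAAGCCTCATGAAATCTCAGAGCCCTTTTAAATACAGCGTCTGGACCAGT
GCACGTGAGCCTCTGGAGGATTTTTTGCATCCGGGACCGAGCCGCGAGCTATACAGGCGT
GACACAAAGGTAAAAGAGAGGAGTACAGCGGAGTTTTATACCTCTCACGCGCCCGTACGT
GTGAATAGTGGGGCATCTTCAGAAGCGATTCCTACACAAACTCCGGCCTTTCAACCCTCA
TTTACTCGAACCTTTCTTTACTCTAAAGAAAATACAGACATACATGTAGTTAGCGTCACC
CACGAACACTCTAGGGCGAGGTCGACGCTGCGGTATCCGTCCCCTGATAATTGGCGACTT
GCATGCTGCAGGCCCAAGGGGGAACGAAGTCTACGGTTCCGGACCTTTGACGCTCTTTCT
AAAAGAATATTCGGTCATTGTGTGCGTAACAGCCTAAAACTTTTATTCTGGTGCCCAGAA
AGGTTTGTATTGCGCATAGTAGTGTGCAGAGTACCTGCTAGTCTAAAGTCTATTGACAAC
AATACTCACGTAACTCGGTCCACGTTTGACCAGCTTGGCCCACCCCCAGTGCGATACATT
AACGTCCGTTATAAAGATACTTCGTATCTACTCCCATTGAACCTTTCTAGACAAGCCGAT
GAAAACTATAAGTTCTGCAAAAACACGCGGACAGGCGTCTGGTCTATCGGAAGGGCGGTC
CCAATCCGACCGGCCAATGAATGTAGCTACCGAACCGTCTTGCAAATTACAATTATCACG
CTGACCCAAATGAGGATCGCAGCCTACGAGGTTCACCGTCAGGCGGTCTTGGCGCGGAAG
CTGCAGGCCGTCCGGAAGAAGCTCACACCGGATGTCAGACCCTTAGCTCGACGCCCCAGT
TATCCCGATGATTCGTCCCCGCTACAAGAGCTGATAACATGCTTCTTCTACACATCCAGT
CCGCGACTCCTGACGCCCATTGACGCCCTGACCTTGGGGACATCAGGGGTCACAATCCGT
TGGGCCCAACACCGTAAGGACTGTCCAACCTTAAGCAGACAAACCGCCTCAGCTCTGAGT
TCTTTACGCCCCGCTGTCCATGCCTATCTTATATCCCATACACTCCACGGTCAGCTCTCG
CGGCCCCAAGAACTAGCGCAGGACCGAGTGCTACGGTGGGGTGGTACATCAAAAGCGCCG
AAGTCAGTTAAACTAGCCCAATTCTGGGACAGCGTGAGTCGGTTACAGAGACCAAGAAGC
GCCCGGACAGTCAGTGACTTTCCGTCGCTCCAAACTTATTTACTGTCGTATCTTCAAGCC
CTATTGCTGTACGTATTCGTCATCTATCATCGTTTGGTGTATACTACCCTGTCGGTCGAC
CGCTCAACGTACGCTATGTATGCGAAGAAGCGAGCTAAGCTATGGGCGCATGCCACTGGG
GGATGTCTTAGGCGATGGCCTCCCGCAAAGTTAGATGTCAATGGCTGTCGGCGGGAAGGT
TGCCGCCATAACTCGGAATCGAGTCTGAAGCTGGTGACGGGCAATGTATTCGCGGGCGGG
ACATTACGGTCGCTAACGAACAAAAGTAAGCAGGTGCTTCTGCTACCACATAATACCCTA
GACGATACCGCCGGCCATAGCCGAACAATGATATGCCGTAGCAGTGGCCAAGTTTTCAAC
ATTACTCTCTTTCGCCCGGCATCCAGGCTTATGGCGGAGACTGACGTAGGCGAGGATCCA
TATTTTTTACCACGAGCACAACCCACTATTAGATCGAGACTCCGCCGTGTCTCACAAGCA
CCAACCAGATATAAGTTCAATGATATAACCCCTGCCGCCATCCTATCCTTAATCGTTCAG
CCAGAACCGAGCGTCGTCCACTTACCGAAAGCTTGCATCGCTTTGAGTGGTGACTTATTT
ACCTGCCATCCACTAGGGGTGAAGAGCCAGAGATACATCCAGCAGAGACTTACGAGTCGT
GTCGGTTTCTTTGCCTCATTCGTATGCCTCCGGCAGGGCGACTGCCGAATCCCGGGGCTG
AGTGTGCTCGCCACCCATTGTTTGTTGCTCGCGAATCTTGATTCACCCAGGTACTATCCC
TGCAGGGGCCGCGAGATTTTCCTCTTGGCTATGCGGAGGATATTACAACGGAGATGCGCC
TCACGCTCGACAACTTGGGAAGCTGTTTATACCACGAAAGTGTCGATCGGACCTGGGTTC
TACCACAGTGTAGCGACTTTTCTCTCTCCAATAGATCGGCATTTTCAATCAACCTCGTCG
GACCTCCGTAACTTGTCACAACATATGTTCAGTCTTAGAGTGCTACACGTATTGAGAAAA
TAA
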