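>synthetic_stripe_transcript
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
CACGACTTTTTTTTTTAAGCCCGTGCTCGTCCGTGCAATGGGCGTACCCATGTGTTATGT
TTAGACCCAATTTATGGGAATTAAGATGGGATACGCGGCTGCCAGAGTAAACACGCGATA
AATGACGCGGACTTTAACGTAGAGTACATTTAACTCGCCACATTGATTATGGGAAGGAAA
CGATCCTCACCAGCCCATACCAGCGGAAAGGCCTCAGTTTTTCCACTTAAAGATAAACAA
AAAAGGGGCCAGCCACGCTGTTTCGCATTAAAAACTACACTGTCCAGGTCGACCCGGCCG
CTGTGGATAGCCCCGATTATGATCGAAATAAGGTAGTTCGGTAATTCAGACCTTTGTTCG
CCGAACTAAAGCGTCGGGCCGAACTACATCGAACTAATGACAACACTCTAGGGCGAGGTC
GACGCTGCGGTATCCGTCCCCTGATAATTGGCGACTTGCATGCTGCAGGCCCAAGGGGGA
ACGAAGTCTACGGTTCCGGACCTTTGACGCTCTTTCTAAAAGAATATTCGGTCATTGTGT
GCGTAACAGCCTAAAACTTTTATTCTGGTGCCCAGAAAGGTTTGTATTGCGCATAGTAGT
GTGCAGAGTACCTGCTAGTCTAAAGTCTATTGACAACAATACTCACGTAACTCGGTCCAC
GTTTGACCAGCTTGGCCCACCCCCAGTGCGATACATTAACGTCCGTTATAAAGATACTTC
GTATCTACTCCCATTGAACCTTTCTAGACAAGCCGATGAAAACTATAAGTTCTGCAAAAA
CACGCGGACAGGCGTCTGGTCTATCGGAAGGGCGGTCCCAATCCGACCGGCCAATGAATG
TAGCTACCGAACCGTCTTGCAAATTACAATTATCACGCTGACCCAAATGAGGATCGCAGC
CTACGAGGTTCACCGTCAGGCGGTCTTGGCGCGGAAGCTGCAGGCCGTCCGGAAGAAGCT
CACACCGGATGTCAGACCCTTAGCTCGACGCCCCAGTTATCCCGATGATTCGTCCCCGCT
ACAAGAGCTGATAACATGCTTCTTCTACACATCCAGTCCGCGACTCCTGACGCCCATTGA
CGCCCTGACCTTGGGGACATCAGGGGTCACAATCCGTTGGGCCCAACACCGTAAGGACTG
TCCAACCTTAAGCAGACAAACCGCCTCAGCTCTGAGTTCTTTACGCCCCGCTGTCCATGC
CTATCTTATATCCCATACACTCCACGGTCAGCTCTCGCGGCCCCAAGAACTAGCGCAGGA
CCGAGTGCTACGGTGGGGTGGTACATCAAAAGCGCCGAAGTCAGTTAAACTAGCCCAATT
CTGGGACAGCGTGAGTCGGTTACAGAGACCAAGAAGCGCCCGGACAGTCAGTGACTTTCC
GTCGCTCCAAACTTATTTACTGTCGTATCTTCAAGCCCTATTGCTGTACGTATTCGTCAT
CTATCATCGTTTGGTGTATACTACCCTGTCGGTCGACCGCTCAACGTACGCTATGTATGC
GAAGAAGCGAGCTAAGCTATGGGCGCATGCCACTGGGGGATGTCTTAGGCGATGGCCTCC
CGCAAAGTTAGATGTCAATGGCTGTCGGCGGGAAGGTTGCCGCCATAACTCGGAATCGAG
TCTGAAGCTGGTGACGGGCAATGTATTCGCGGGCGGGACATTACGGTCGCTAACGAACAA
AAGTAAGCAGGTGCTTCTGCTACCACATAATACCCTAGACGATACCGCCGGCCATAGCCG
AACAATGATATGCCGTAGCAGTGGCCAAGTTTTCAACATTACTCTCTTTCGCCCGGCATC
CAGGCTTATGGCGGAGACTGACGTAGGCGAGGATCCATATTTTTTACCACGAGCACAACC
CACTATTAGATCGAGACTCCGCCGTGTCTCACAAGCACCAACCAGATATAAGTTCAATGA
TATAACCCCTGCCGCCATCCTATCCTTAATCGTTCAGCCAGAACCGAGCGTCGTCCACTT
ACCGAAAGCTTGCATCGCTTTGAGTGGTGACTTATTTACCTGCCATCCACTAGGGGTGAA
GAGCCAGAGATACATCCAGCAGAGACTTACGAGTCGTGTCGGTTTCTTTGCCTCATTCGT
ATGCCTCCGGCAGGGCGACTGCCGAATCCCGGGGCTGAGTGTGCTCGCCACCCATTGTTT
GTTGCTCGCGAATCTTGATTCACCCAGGTACTATCCCTGCAGGGGCCGCGAGATTTTCCT
CTTGGCTATGCGGAGGATATTACAACGGAGATGCGCCTCACGCTCGACAACTTGGGAAGC
TGTTTATACCACGAAAGTGTCGATCGGACCTGGGTTCTACCACAGTGTAGCGACTTTTCT
CTCTCCAATAGATCGGCATTTTCAATCAACCTCGTCGGACCTCCGTAACTTGTCACAACA
TATGTTCAGTCTTAGAGTGCTACACGTATTGAGAAAATAA
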