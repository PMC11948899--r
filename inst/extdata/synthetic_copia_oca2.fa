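>synthetic_copia_oca2
TATCTATCGCCAGGCAGCCAGCTGGAAAGGTAATCGCTGACCTACACTTGGCCCGACGGC
ACTTCCCATGGTACTATACTGACCACTGCGTCGATAACCAGGATGACATATACCTAGTAT
GGCGTTCAGTAAGGAGGGTTCCCCACACTCTGATCAATGCCTCTATTTTGTAGTCAGCGC
CTGCGGACAACAGTCGGTCAGTGGGCAGCCAGATCGTAGCCCCCTTGCTGACGAGATCTG
ACCGGGGTCTAAGTCCATCATGTGAGCCATCAAGCATTCGGATTTTCCATTTCATACGCA
AGAGACTAGATACGTCGAGCATGCTAGAACGGCAGCCCAAATTCCCTAGTCGCCTTAATG
GTAGTTTTCACGAACTTTAGAGCGGGCCGGTCTGTACATACGTGGTATACGCTGCTGTGC
ATTGGAACCTTTTTCACGCTTGTGATCGACGTTATTGTACGCCCCTCTAAAGTCCGTACA
CCCACGATGCTATCCCCTCCTTTTAAAAGACAGACATCAGGAATAGCTTATTCAGACCTA
CGAGCTCTAAGTGCTACTCCGTCGTCGACACTCCTGCTACGTGAAGTGAGTGGCATAGGC
AAATAAAGAGGTTAGGACCCGCGCAGCTGATAGCGTATTTGGTAGTTAGCCTCGAATCGG
ACATCACTGAATCCCATCTAATGCTGCTCTCCGCTAGGGGCGAGGGTTCCTGCTAAGTCC
GGTGTGACGGATACGACCAAAGATGGAGTGAGTAGTCGATCAGAGGGGTGGGTGACGACT
AGGTCAGGACCGCCGTTAGCCTCATTAATAGATTCTAACGGCGGTGTATCTGTGGCGGGG
ACTGCAGCACCAGGCCGAACAATCCGACGTAGCTTTCAGATGCGAGCGCTAGTTGACCCG
AGATTTCACTGTAGCCACTTACTTAAGGACACTCGTCTATCTAGCGGATGCAAGCCCGCT
CGCCAAAGGGGGCGGCCTACTATCAATGTGCTGAGGCCGACTTTTTTTTTTAAGCCCGTG
CTCGTCCGTGCAATGGGCGTACCCATGTGTTATGTTTAGACCCAATTTATGGGAATTAAG
ATGGGATACGCGGCTGCCAGAGTAAACACGCGATAAATGAAAATCTCCTTGTCCCACTGA
TACCCGTCGTCGTAGAGTCGCTGATCTGGGTGTTAACGGGGCCGAAGGCATTAACCAGAT
TTATGACGTTAGAGCTAGACACTATTCTTCTCCATCTAAGTACGTGAACATCTCCTCACT
AGATTCCTGCCACTGGCGCGCCTATCACTGAGTAATTGTTTTGCTGATATACTTGGTTTC
CGTGTTTCGGCACCCCCAGAGGTACAAGTTCCATCGAGCCGTGGATACGTTAGGAGGTTG
ACTTTTAGTGTATGTTTCCCCTGTTCATTAGTCGTTGTACATGTTCGAAGACTAGCCCTT
TAAACAGGAGGGGAATTTGTGTCGGCCCCGGCTACGGTGTGGGCGTTTACGAATTCTGAA
GCGAGCGAGTCAAATTTTCACGTCGTCCGAGGGCAAGGGTACGACTTGGTGCGCGTCAGA
AACACATCTACCATACTACAGAGTCAAGGGCACAACTTGGGGCTAGCGCTGTTGCAGGAC
TAACCACCTTTCATTCAAACGTGGAGCTCTCTGACTGTCCTAGTGCACGATAATTGCGGC
AACTAGCGTAATATTGGCGCAATATTCCAATGTTACCCAGTGAGACTGTACAACTTCCGT
TTCAAGTGCTCGTCCCTCACCATTGTGCAATAGACATATACCGCACATCGGCGACCATAA
CTGAGATGATGTGTACGGGTTTCGTCGGCTCATGATATGATAGGTAAAATACACCGCCCT
ATGGGAGGGAAGGCATGCGGGCAATAGCCCCTTGCGACCACAATGCAGTGATATGATCGC
CACATCCAGTACGGAAGTACGTCCGGTTCGTTAGCGACAGGTCGCTAATTCATAAAAGTA
CTCCGCTTTTCAGGAGCGAAGTCGTTTCACTACTTGCTCCGAACCAGGCAAGATTGAAGA
AGCCCATAGCAGACACTTGACCTGTCCCATATGGTCCGCCCAGTCAGAGGACTGTAGACG
TGTTCAAGCAATGTTAGTCCACAGTCCTCTATAGGCATCGCTGATTTTAACGTTTGATTT
CCAAGGACCAATGTGATTGTACCGCCTGAAACCACGAAAGTGACCCTGAGACGTGCACTT
GTGCCAGCGAATCCGGAACAAACAAAACCATGGCTGTCGAGGTGTAAGATCAGGACCGGC
TACTTCCAGATAGTGATCTGATGCCCCTGACTCCTGAAGGCCTGAATCAGAGGTTTGCCT
GCAGAGGGGACTTGAATCCGTTTAGGAACCTATCTGAGCCCATGGAAAAGTTGGCAGGGA
CATAAACTCTAGTGGGGCATCGAAGGAGCTATTTAGCGTCACTATAACATCGATCACAAT
TCTTTTGTCTGAATTGATGGAGGGGCTTCAGCGCGGTCTCCGCGGACTTTAACGTAGAGT
ACATTTAACTCGCCACATTGATTATGGGAAGGAAACGATCCTCACCAGCCCATACCAGCG
GAAAGGCCTCAGTTTTTCCACTTAAAGATAAACAAAAAAGGGGCCAGCCACGCTGTTTCG
CATTAAAAACGGCGCAAGACAGCCGGATATCGGCAGCCCATCTTGGAGAGCCAGACGCAT
GAGGTGGGGATATCTGGTCACGTAGCCTTTGCACGCGGATATCCGTTCGGACCAAACGTA
AAGAATCGAGAACTTGGTCTACAGCGACCGTTACAGGCGCGCTTACCGACCGTAACAGAT
CTCTGCGGTGGTTGTAACAGGTTATACATGACCGGCGTCTTAAGCCGCGTAGGAAGTACA
TGTTATAACCAGGCGTGATGGTATTAGGGTTCAGAGTTCATGGACCAACGGTCATAAGGA
GGTCTGCCCTCGTGATATTCAGATCGCACTAACTGATCGTTGCGGCCGTATACAGGAGTC
GCTCTCGCGTTTGCAATCGCCGATCCGTCGGCCTAGGCTTGTATCTGGAGGACTACGGAA
ACTCCGGTACCCCATTTGGCCTGTCTTCTACCGGTGGATCTATAAGATAGTGTTACTGTT
TATCCACATCAAGTGTGCCCGAGCATGCGCGAGCGGCCGCCCTCCTTGGCTCCTTCTAAA
TGCGCTCGACACAGACAAATGCAAGTTCGAAAGCACCCCACTAGATCTCCAAACACTTCG
CCAACGCCTCGTGGACTATCTGCAATGGTAACAGGAACCGTTCATTTGTTCTACACCCGT
AATGGACTTAACCGGTATATATCGTGATTGTTGGTAAGACTAGTCTGTAAATTTAGAGAG
AGACGGGCGGACTGTCAGAGGTAAGGTCTCTTGGGTGGCTTCATAGAGTAGGTTAGGTTG
CTTGTATGGTTGGCTACACCATTGGGGTAACCGGCGGCGTTGTGTGTCGAAGTGGGCACT
GGATTGATTACCACTAGCCCCGTAGTACGGCTATGAAGTTATTCGTCCGCGGTATTTGTA
ATGTGATCGCCTACTGTCGGAATGTTGTCATGAGATCCACTGACTGGAAACGTACATGCC
CGGTTGGAAATTCAACTTCGTGCGGGAGTGCTCACGCCGACACAAGAGCGGCCACTAACC
ACGTCAGGGCCTTCTGGCCTACGTAAATTCGCGCAAATTACTACCTGAAAGAACAGGCAT
AGGATTACGCGCAAGTGCCGTCTGTGGAGATAGAACGCGCGAGAGCAGTCAACGTACGAG
AGTTACTTGCCTGTCGTTACTTCTAGGATAGTCATTGAATGTCAAATCAAAAATTTCCCT
ACCCGGTCAACGCAGGGACCATAGGTCACTGGTCGGTGAATAATGGGACAACCTTGGAGG
TCGGTGCTAGGATCTATCTCAAGACGGAAATACTTAGGACACTTAGGGGTTAGATACGAA
GTGTATACAAGACTCCATAAGGCTAATTTCCCCTGCGTAGTACACTGTCCAGGTCGACCC
GGCCGCTGTGGATAGCCCCGATTATGATCGAAATAAGGTAGTTCGGTAATTCAGACCTTT
GTTCGCCGAACTAAAGCGTCGGGCCGAACTACATCGAACTAATGACACTAGATAAGCACA
AATCTAACCGTTTTGCACAACCTAAGCCATGTACTCCTGACTCCTGGCATAGACACGCTA
AACCACGGTGAGGGGTTCGGAAAAGCCGCCCTGTCAAATCGCCTTACTGACTATGTATGT
AAACCGTATTATGAACCACTCCAAAGAGGTACATAATGGCGTCCATACTTTTGTGGTTTT
TCCTAAGGCCACTCGTACGATGCTGCCTATTAGTCTTTTGATGGTTAGACGAAACACGCT
AAAACTAGTTGTAAACTGGTGTCGGCTCCGGAATCCGACCCGTCAACATGGCAGCTCTGG
TGGGCGTACAAGTGCAGGCTGGTTCAGCCTCCAACGACGCTTTAAGGAGCCAAAATAACC
TAAGTCCTGGGCAGAGAAATGGTTGAACATTGAAATTCAGTATTCAAAGATTATCTCCCA
AGGTAGAGCAATAGCAGCACGGCAACCAATCTACCTTGACGCAGATTCGGTGAGTTCAGC
CTTTGACACCAGATAGCTCGCACGAGCCAAAGGTGTTAGTCCTCATAACTCAGTGACCAG
AGATCCCTCCGACTTTCACCGTAGGAGCAGTTGTAAAGGGTATGTCCCCTTTGGATGTGG
AAACGGGGGGGGAATTAGAACCGAGCTCAATCGGAGGCGTTTTCGCGTGTTGAGTTGAGA
CACTTAATGAATAACTATAGGCAGTTGACACACTTGGTGTGGTAAATAGTGCCCTATCGC
GACGTAAAGATAGGTTTACCACGATAACCATGCAAAGGTGCAGGTTCTATGTTTCCTACC
GTGGAACGGTGTATTATCTTACATAGAAAATTGGAGAAGTAATACAACCCCTTCTCTGAT
GTAATGATTCTCTGCTCGGACCCAGGTGGTGACAGTCTCGCATCAAGGTGTCGGGGCGGA
TTAGTGGACGTCAAAATACCTAGGCATTGAGATCAGGGTTAGGCTCTTGACGGTCATCCG
GGGGGACAACCTTTATATGATTTTTAATCGGTCTGAACCGGGTGTACGCGATAGCCACGA
ACTTATATACCTCGGCGCGAACAGTACTGCGTCACTCAGCCCCTAGCGACTCGTGTCGCT
AGGACATGCGGCTGATGTTATCGTCAGCAGTCCTGAGCCCTAAAGTACTATTTGCTCCGG
ATTAGCCTCTTATATACAGTACTCGCGAGGAGCCATTGACCAATGAGTCGTCGTGCAAAC
ATACCATTAAGACCCATCTGTCCTTTAACTACGCCATCAACTAGCGCACAGTAAACTGTA
ACCGCCCAAGCGTGCAGTGTTATAATTAAAACATTATGGCATCGACATATTTCGCTTGGC
ACTCGTGTCATCCCCCTAGTAAATAATACAAATTTCCACTCACGCTTTTTTAGGTGATCT
GACTGCAGTTTTTATCTATCGCCAGGCAGCCAGCTGGAAAGGTAATCGCTGACCTACACT
TGGCCCGACGGCACTTCCCATGGTACTATACTGACCACTGCGTCGATAACCAGGATGACA
TATACCTAGTATGGCGTTCAGTAAGGAGGGTTCCCCACACTCTGATCAATGCCTCTATTT
TGTAGTCAGCGCCTGCGGACAACAGTCGGTCAGTGGGCAGCCAGATCGTAGCCCCCTTGC
TGACGAGATCTGACCGGGGTCTAAGTCCATCATGTGAGCCATCAAGCATTCGGATTTTCC
ATTTCATACGCA
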