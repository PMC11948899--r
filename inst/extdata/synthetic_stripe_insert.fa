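>synthetic_stripe_insert
CTTTTTTTTTTAAGCCCGTGCTCGTCCGTGCAATGGGCGTACCCATGTGTTATGTTTAGA
CCCAATTTATGGGAATTAAGATGGGATACGCGGCTGCCAGAGTAAACACGCGATAAATGA
CGCGGACTTTAACGTAGAGTACATTTAACTCGCCACATTGATTATGGGAAGGAAACGATC
CTCACCAGCCCATACCAGCGGAAAGGCCTCAGTTTTTCCACTTAAAGATAAACAAAAAAG
GGGCCAGCCACGCTGTTTCGCATTAAAAACTACACTGTCCAGGTCGACCCGGCCGCTGTG
GATAGCCCCGATTATGATCGAAATAAGGTAGTTCGGTAATTCAGACCTTTGTTCGCCGAA
CTAAAGCGTCGGGCCGAACTACATCGAACTAATGACA
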