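>synthetic_pri_mir319a_contig synthetic stand-in, 828 nt
CGAAAACAACTAACTTAAAGACCTCGCACGTCTGCGAGGCCCACACACGCGTGGGCATTA
TCCAGATGGCCTATGCAGTCACGAGGTACTTACCTCCTACCGATAGGACATTAGAGAGAA
GGGATAACGGCGGAGTTAGCGTCTTAATTCGGAGGAATGGTTTAGTATTCACGCAGTTAC
CTCACAACTTACAATCGCCACAATAAGCCCTGGCAAAAAGGTAATAAGCGCAGTAGATAA
ACTATGCACTGCGGACAATTAAGATCGCGAGATTTGCTAACAGACACCTGGAAACGTACA
AACTGCAGGCCACGTGTTTTTAAATTGCACATCATAATCGTAGATCGTGTACATACGAAA
ACGGGGCGATGTCCTACACCAGATATACTGGTCCCATAATTCTTGAGACAATGTTTCCCG
GGACAACCAACAAAGTAACGATCCGAGATCTCTATCAAAAGAGACTTGTAGAATGCACGT
CCGCAAGTCGGGGTAAAACTCGGCCTTTATTTAAGAAGCATTATCGGATACGGCAGGGTT
AGGCGCGCGATGCCGCGCTCCAATACCCCGAGGATTAACTGTGGCCCTTATAGAAGACTG
CATATCCTTGGTTAATTTTACAAACCAGTATTCCAGTCTCCGATACGACCCCACATTGGA
CGCATGCTACTTGTCAGGCAAGTGTACCAGCAGCATATGTCAGGATCGGTCGCATAGCGA
CATTGTTCAGAAATGGTCCCGGCGAGACCAAATCGCATGAACTACGCGAAGGCATTGAAT
GGTACTCGCGGTGCCCACCGCTCATGAGGCATGCGTAAGACGAAAGAC
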