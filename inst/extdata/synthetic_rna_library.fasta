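>6S RNA
GCCACGTTCCGTGGGCTCTTCGGCCTTCTCGCGCCACGCCCCGATAACCTTCGGGGCGTG
GCGCATGCCTCCCGATCCCAGCAGACAAGGGCGGAAAATCCGCCCTTGTGATGAGACCAG
CCCAAAGGGGCGAA
>tmRNA
CTTTTCTGCGGTTGTATGCTGTGGGAAGTCAGCACACTTCAGAGGCGGTACAACCTTTTT
GTACCGCCTCTGACCCTTAGTAGTTATCGGAACCCTCAGCTAACCGTAGCCCTGTGGTGA
CTGCTGCGACT
>RNaseP
AGCGGGGTGCAAAAACGAAGTTTTGTTTTTGCACCCCGCTCGCTGGAGGGTACAGACGAA
ACCCACCACAGGTCGCCCAGCTATAGGACTTCAGGCGCATTTATGCGCCTGA
>FMN riboswitch
AGTCCGAATACAGGCCCAGGACGCGCATTGTAGCGCGTCCTGGCCAATGGTCGGCACTAC
TCCTTCGTCACTC
>TPP riboswitch
CAGACCTCGGTCCATGGACCTTAAGGGTGCCTAATGCACCCTTAACTCGGTCACACCATA
CCGAGGGAATAGTCTACGTC
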