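>sCOIA offset=401 frame=COI
CTCCCCACCCAGGTTGGACCCTTAGCCACTTGGTATACCGGTAACCACGGGAAGCACGCCGTGCCAACTGTCTCCCGCTCCGGATATCCTGGGTTCATCGGTAGACAGTCCAAGTCAATTCCCTTAATGAGTTCGGTTGGTTTGATACTCTTGTTTTGAATCAGTCTGTTTGTCAAAGTCACCTCACGCGGGACTAAGGGCCAGAAAGGGTCTGGATGTCCAGGTGGAGATGAGTTACAG
>sCOIB offset=1001 frame=COI
TCGTAGGGCGCTCTGCAGGTCACAAGTGCAGCCACTAGCATGTCTATCATGATCTAAAAATGGAATGGACCGCAGGTATGCCATGGGAGATGTATCGGGTCTAGCCCGGATGGCTGGAATGGCACACGGGGAGCATCCCTACAGCGTGACCTGACGTAAACCAACCTGCGGTAGGCCGCGGTTTCGGCTAGACACCGTCTGCGGCAACGAAGTGATGATAATCTGTGTAAGGGCACAGCTTCGCCGTTGAGCAAATAAAAAAATCCGTGTGTGATCGCAGCAAATGATAAGTTTTGATGGTGAAATGTTAGGATTGGAAC
>sTpiE offset=1 frame=TpiE
GAATCGAAGACGCTTGCACGAATAGTCGTCGGTTCTGGGGCCGAGAGAGGGACGTGCACACCCCAGTTGAACTGGCCCACATTACTACACTCGGTATCATTCTTTTTGGGCGCGGTCACTGGTTGAAGAGATACTGAGCCCTTGTGGCAGGTCGTCATTCAATGTCTGTGATCCGCCGAAAAAGTAGGACGCACGCTACT
>sTpi140 offset=1 frame=Tpi140
ATACGGAGAAAGCTCATAGCTTTCTCGTCTCGGCATTATCGCCTCAGTGGCCAGGACTGAATCCTGAACAACTAATAAGGCTACATCTTTAAACTGGAAGAGGCATGCTACAACTGATCGATGATTTCATCCGACCGAGA
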