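>Kdm8_transcript_synthetic synthetic stand-in transcript (1200 nt)
TCGCATCAAATATACAGGCTGGGTGAATTTAGAAAGTAACCTGGGATGTGGAGCAATGCT
GGTTACATATCAGCTCCCTACCCGGACATCCCACCGAGCTAATCAGCACAAGAGCCCCTA
GACCATTTAAGAGTAGCTATAACTTTCTCTGTTGCACAAGTCTTGGATACAAGCCACGAG
CCTGCGACACTTGAGAGTCGACATGGTAATCTGCCTCGTAGCGGACCACCGATCAAGATC
CAAAGATCACCTGCTGATTTCCATGTGCGCAGTTATTCCGAGCAGCCGAAAATGATGGAT
TGTCGCGGGCCTTATAATAGATCACCTGCCAGCCTGTCAAATTAGAAAATGACTACCAAA
TGTTGGGTTTAAGTCCAAGGGCGCGGACGGATCAAAGGGTATAGAGTACCCTAGTCGCTT
ACTAAGTAAGGGATAGAGATCATGGGGTGGTCTACGGGCCGTTATGTCCAATTGTGTCGG
CACGCGGCGAGCCTAACAGCATAATTAAAGCCCCCCACTTTCTTGCTCCGGGCTATCTAA
CAGATTCTGACTTCGTAGTGACTTTCGGACACTTTGGACTCTCTCACGTGTGATGTCTGT
CTAACTTACTGCCTTAATGACGAGATCACTGAGTAGCGATCTACTAGTCAGGATGTAGCG
TTTGCAGAGTCCTGCTATACAGACGAAGTGAGGAGGCTCAGCACAGAACTCGGCTGCTTT
CGTGGCCTTCCGAAAACGGAGGCCAGTGAGGCCCACTCGACCTGGCCGACCGTGGATATC
GAAGGGCGTCTCCGTGATGCATCTTTCCCCCGCGGGAGAAGAGCGAATTGAACGCAAACG
ATTGCGCTACACGGTGTTGGTTGGGGTCAGGAACAGACAGCACGAATCTGACGGTCTCCC
TTCACACTGTCATTAGTGTTGCCAGCCGCGAGGTAATTTTGTTGTGAGGTCTGGTAGTCC
GTTGTGCAACATGCGATCTCCATCCCGGCATAAATGTCCGTGAACCGTGTGCTGCTGACG
TACTAGAAGTCCCCGACGCCATTCCCCGCCCGCTCCGCCGTATGTATGTCGAGCTCGTTC
GTTATTTTTGCAGCCTGTAAGTCCAGACGCATTTCGCATACGAGGGCTAGAGGAGCAAAT
GGGGTAGAATGCCTAACTTAGGCGCGCGGCGTTATGCCGTTGGCGCTGTACATAAGCGGA
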