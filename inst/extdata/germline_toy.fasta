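>TVH1-1*01 segment_type=V cys104_offset=297
CAGGGGGAACGAATTGTGGAGGTGAGACGGCACCTACACCATGCTACATTAGGGATACTCACGTGTCTATTTGTTCCTGATAGTGCCGTACTTCACGATCTACATAGACGATTTCACGGCTTAACTGATCCTCAGGATCAGCATCTGAAGATTGAATTGAGTCTAGTCATGAAGCGCTTCCACAGTATCACGGAGCGTCCCGTGCTTGGCAAACTCATATTAAACAACCGAGCGAAGGCCCGCCTTGTTTGGCCCTTAATTCTGTCGATGGATGATCGTATTTTCCACGGGTGCTGCTGT
>TVH1-2*01 segment_type=V cys104_offset=297
CAGGGGGAACGACACGTGGAGGTGAGACGGCACCTACACCATGCTACATTACAGTTTCTCACGTGTCTATTTGTTCCTGATAGTGCCGTACTTCACGATCTACATAGACGATTTCACGGCTTAACTGATCCTCAGGATCAGCATCTGACAATTGAATTGAGTCTAGTCATGAAGCGCTTCCACAGTATCACGCGGTGCCCCCGGCTTGGCAAATATATATTAAACAACCGAGCAAAGGCCCGCCTTAGTTGGCCCTGCATTCTGTCGATGGATGATCGTATTTTCCACGGGTGCAGATGT
>TVH2-1*01 segment_type=V cys104_offset=297
CAGGGGCATCGATTTGTGGAGTGTAGATGCAAGCTCCACAATGCAACATACGGGTTTCGAGCTCCCGGATTTCAACCTGATAGTGGTGTACTTTGCGATCTACATAGACGATTTCACGGCGTCAACGATACCCAGGATCAGCATCTGCTTCTTGAAGTGCAAATACCACATAAGCGCTTCACCAGTCTCACGGAGCGTCGTCGGCCTGGCTATCTCAGAGTTTGCCTCCGAGCGACTGCCCGCGGGAATAGCCCCTGCGCACTGTCGCTTGATGATTCAATTCACAAAGACTGCAGATGT
>TVH2-2*01 segment_type=V cys104_offset=297
CAGGGGATCCGATTTGTGGAGTGTAGATGCAAGCTCCACTGGGCAACATACGGGTTTCGAGCTCCCGGATTTCAACCTGATAGTGGTGTACTTTGCGATCTACATAGACGATTTCACGGCGTCAACGATTTGCAGGATCAGCATCTGCTTCTTCGTGTGAGTATACCAATGAAGTGTTTCGCCAGTATCACGGAGCTACGTCGGCCTGGCTATCTCAGAGTTTGCTCACGAGCGACTGCCCGCGGGAATAGCCCCTGCGCACTGTCGCTTGATGATTCAATTCACCACGACTGCAGATGT
>TVH3-1*01 segment_type=V cys104_offset=297
CAGGGGGCCCGACACGAGGAGGTGGTTCGGAAGATTCACCATGCTACAGCGGGGGTCCGAGCTCCCCTACATGTTCCTGATAGTAAACGTCTTTGCGATTATCATAGATGCTTTCACCACGGATTGGATTTGCTGGATCAGCATCTGCTTCTAGAAGTGAGTCTACGACGGCTCCGCTTCCACTGTCACGGTGAGGACCCCCGGCCTCTAAAACTCAGAGTTTGCCTCAATGCGAAGGCCCGCTCAGTTTATTTCTGCATTATCTCGATGGATGATCGTATTCACCACGACTGCAGATGT
>TVH3-2*01 segment_type=V cys104_offset=297
CAGGGGGCCCGACACGAGGAGGTGGTTCGGAAGATTCACCATGCTACAGCGGGGTTTCGAGCTCCCCTACATGTTCCTGATAGTAAAGTCCTTTGCGATGTTCATAGATGCTTTCACCACTTATTGGATTTGCAGGATCAGCATCTGCTTCTAGAAGTGAGTCTATCGCGGCTCCGCTTCCACTGTCACGGTGAGGACCCCCGGCCTGGCAAACTCAGAGTTGTCCTCAATGCGAAGGCCCGCACTGTTTATTTCTGCATTATCTCGATGGATGATCGTAGGCACCACGACTGCAGATGT
>TVH4-1*01 segment_type=V cys104_offset=297
CAGGGGAAACGACACCAAGAGGTGGATGCACGGCTATCCACCGCTACATTAGGGGTCCGAGCTTCTCTATTTGGTTATGATAGTGGTGTACTTTGCCCCCTACATAGACGAATGCACGTCTTAAACGATAAACGGGATCAGCATCTGCTTCTAGAAGTGAGTCTAAAATATAAGCGCTTCCACAGTATCACGGAGCGTCCCCGGCCTGGCTGCACCAGAGTTCATCTCCACTTAAAGGCCAGGGGGGACTATCCCTGCATTCTGTCGGTGGATGATCGTATTAGTCACGACTGCAGATGT
>TVH4-2*01 segment_type=V cys104_offset=297
CAGTGGAAACGACACCAAGAGGTGAGAGCACGGCTATCCACCGCTACATTAGGGGTCCGAACATCTCTAGTAGGTTATCTAAGTGGTGTACTTTGCGATCTACATAGACGAATGCACGCGTTAAACGATAAACAGGATCAGCATCTGCTTCTAGAAGTGAGTCTACCATATAAGCGCTTCCACAGTATCGCAGAGCGTCCCCGGCCTGGCAAAGGAAGAGTTCATCTCCACTTAAAGGCCAGGGGGGACTATCCCTGCATTCTGTCGGTGGATGATCGTATTAGTCACGACTGCAGATGT
>TVJ1*01 segment_type=J fr4_motif_offset=0
TGGGGCCAAGGAACCCTGGTCACCGTCTCCTCA
>TVJ2*01 segment_type=J fr4_motif_offset=0
TGGGGACTGGGAACCACGGTCACCGTCTCCTCA
>TVJ3*01 segment_type=J fr4_motif_offset=0
TGGGGCCGTGGAACCATGGTCACTGTGAGCTCA
>TVJ4*01 segment_type=J fr4_motif_offset=0
TGGGGAAAAGGAACCCAGGTGACCGTGTCCTCA
>TIGA*01 segment_type=C isotype=IGA
ATAGCCCTAGCCATGGAGCTACCATAGTTAACGAATGGCTACCGT
>TIGG*01 segment_type=C isotype=IGG
CGTGGATGAACAACAGAGCGAACACTACACGAATACTCAAACCAT
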