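name	gene	forward	reverse	annealing_temp
PS1	COI	ACCTGCCTGCCGTATTTGGYGCYTGRGCCGGRATAGT	ACGCCACCGAGCCARAARCTYATRTTRTTYATTCG	NA
FishCB1	cytb	TCCTTTTGAGGCGCTACAGT	GGAATGCGAAGAATCGTGTT	NA
FishCB2	cytb	ACAACTTCACCCCTGCAAAC	GATGGCGTAGGCAAACAAGA	NA
VeCB1	cytb	AAAAAGCTTCCATCCAACATCTCAGCATGATGAAA	AAACTGCAGCCCCTCAGAATGATATTTGTCCTCA	NA
VeCB2	cytb	AAAAACCACCGTTGTTATTCAACTA	GCCCCTCAGAATGATATTTGTCCTCA	NA
VeCB3	cytb	TTCCTAGCCATACAYTAYAC	GGTGGCKCCTCAGAAGGACATTTGKCCYCA	NA
12S-V5	12S	ACTGGGATTAGATACCCC	TAGAACAGGCTCCTCTAG	NA
Ac12s	12S	ACTGGGATTAGATACCCCACTATG	GAGAGTGACGGGCGGTGT	NA
Am12s	12S	AGCCACCGCGGTTATACG	CAAGTCCTTTGGGTTTTAAGC	NA
MiFish-U	12S	GTCGGTAAAACTCGTGCCAGC	CATAGTGGGGTATCTAATCCCAGTTTG	58
Teleo	12S	ACACCGCCCGTCACTCT	CTTCCGGTACACTTACCATG	NA
AcMDB07	12S	GCCTATATACCGCCGTCG	GTACACTTACCATGTTACGACTT	55
Ac16s	16S	CCTTTTGCATCATGATTTAGC	CAGGTGGCTGCTTTTAGGC	NA
Ve16S1	16S	GCCTGTTTACCAAAAACATCAC	CTCCATAGGGTCTTCTCGTCTT	60
Ve16S2	16S	CGAGAAGACCCTATGGAGCTTA	AATCGTTGAACAAACGAACC	NA
Ve16S3	16S	AGACGAGAAGACCCYDTGGAGCTT	GATCCAACATCGAGGTCGTAA	60
Fish16S1	16S	CGAGAAGACCCTWTGGAGCTTIAG	GGTCGCCCCAACCRAAG	NA
Fish16S2	16S	GACCCTATGGAGCTTTAGAC	CGCTGTTATCCCTADRGTAACT	NA
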