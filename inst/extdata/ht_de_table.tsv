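# Heat-responsive miRNAs reported as differentially expressed only in the
# heat-tolerant genotype of flowering Chinese cabbage (6 h and 12 h of 38 C
# heat versus the 0 h control; two-library exact-test p-values and log2
# ratios as printed in the study report). NA marks a contrast in which the
# miRNA was not significant. Used as a worked example for direction calling
# and set algebra.
mirna	class	sequence	count_0h	count_6h	count_12h	lfc_6h	p_6h	lfc_12h	p_12h
novel_mir27	novel	TCAAGCTGGTGTCTGGATGAGT	155	47	0	-1.71	3.28e-05	-17.23	6.96e-41
novel_mir95	novel	GGTGAGGTCGCTCTGAGAGGATAG	29	0	0	-14.8	1.89e-06	-14.77	3.32e-08
novel_mir149	novel	GGGGAACGACGATTTGTGACACC	143	0	29	-17.1	2.41e-29	-2.25	7.67e-15
novel_mir46	novel	GAAAACTATTCGATACATATGGCC	0	NA	15	NA	NA	13.66	5.58e-06
novel_mir89	novel	AGGGACAGAGGACTGACATGTGGC	107	NA	0	NA	NA	-16.62	1.96e-28
novel_mir105	novel	ACTAAATCTACACCAATATTGAT	85	NA	0	NA	NA	-16.29	9.93e-23
novel_mir114	novel	ATTCTTGAGTCCTTAATACATATA	20	NA	0	NA	NA	-14.29	7.16e-06
novel_mir120	novel	GACTCTAAAAATACCCTTGGTACTT	79	NA	21	NA	NA	-1.85	6.84e-07
novel_mir177	novel	TATTCCCGCGAAACCCACGGC	0	13	NA	13.55	1.82e-06	NA	NA
novel_mir238	novel	CCTGCGGCTGCGGCGATATT	241	NA	0	NA	NA	-17.86	3.46e-63
novel_mir240	novel	CAATGGGATCCGCGAACAGTGCA	17	NA	0	NA	NA	-14.05	4.29e-05
novel_mir243	novel	GCTGATGGAACACTGGCCCGGCCCA	0	NA	20	NA	NA	14.21	1.03e-07
novel_mir250	novel	TATAGTTAGGCGTTAGGCACTATG	104	NA	0	NA	NA	-16.67	1.17e-27
novel_mir255	novel	CAAGCGGTTCAACTGCGGTGCGGT	1494	494	NA	-1.67	5.79e-31	NA	NA
bra-miR156e-3p	known	TGCTCACCTCTCTTTCTGTCAGT	1971	NA	696	NA	NA	-1.51	6.29e-90
bra-miR824	known	TAGACCATTTGTGAGAAGGGA	1026	396	261	-1.39	2.77e-13	-2.01	7.86e-77
bra-miR1885a	known	CATCAATGAAAGGTATGATTCC	1271	396	NA	-1.68	4.82e-31	NA	NA
bra-miR1885b	known	TACATCTTCTCCGCGGAAGCTC	1546	572	NA	-1.42	1.63e-22	NA	NA
bra-miR172d-5p	known	GCAGCATCATTAAGATTCACA	1	NA	14	NA	NA	3.70	1.1e-04
bra-miR400-5p	known	TATGAGAGTATTATAAGTCAC	750	231	NA	-1.7	1.77e-19	NA	NA
bra-miR396-3p	known	GCTCAAGAAAGCTGTGGGAAA	1694	693	NA	-1.29	2.00e-16	NA	NA
bra-miR391-5p	known	TTCGCAGGAGAGATAGCGCCA	335	110	NA	-1.59	3.48e-08	NA	NA
bra-miR2111b-3p	known	ATCCTCGGGATACGGATTACC	30	1	0	-4.75	1.48e-05	-14.72	1.82e-08
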