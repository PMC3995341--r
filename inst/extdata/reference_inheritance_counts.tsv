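pattern	category	N9	9N	NN99	99NN	pct_N9	pct_9N	pct_NN99	pct_99NN
N=9 -> N=9	parental_condition	4503	4545	3023	3063	38.79	39.15	26.04	26.39
N>9 -> N>9	parental_condition	1297	1249	1322	1253	11.17	10.76	11.39	10.79
N<9 -> N<9	parental_condition	951	952	1357	1497	8.19	8.20	11.69	12.90
N>9 -> N=9	no_bias	1321	1368	891	933	11.38	11.78	7.68	8.04
N<9 -> N=9	no_bias	1807	1797	978	952	15.57	15.48	8.43	8.20
N=9 -> N>9	novel_bias	801	776	1403	1184	6.90	6.69	12.09	10.20
N=9 -> N<9	novel_bias	481	464	1359	1538	4.14	4.00	11.71	13.25
N>9 -> N<9	opposite_bias	147	148	552	579	1.27	1.27	4.76	4.99
N<9 -> N>9	opposite_bias	300	309	723	609	2.58	2.66	6.23	5.25
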