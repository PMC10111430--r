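chrom	pos	strand	context	gc_percent	ratio_WT1	ratio_WT2	ratio_WT3	ratio_KO
chr2	2831383	-	CHH	11.94	0.429	0.318	0.350	0.211
chr2	3200390	-	CHH	10.45	0.286	0.156	0.300	0.500
chr2	3200403	+	CHH	11.94	0.333	0.277	0.350	0.375
chr2	8101959	+	CHH	17.41	0.500	0.184	0.248	0.261
chr2	8101986	-	CHH	14.43	0.200	0.292	0.279	0.138
chr2	8102002	-	CHH	13.43	0.278	0.313	0.273	0.233
chr3	5720793	+	CHH	9.45	0.429	0.286	0.185	0.176
chr4	76958	-	CHH	7.96	0.250	0.281	0.317	0.286
chr4	2524803	+	CHH	16.92	0.308	0.306	0.438	0.480
chr4	2524824	-	CHH	13.43	0.143	0.345	0.318	0.375
chr5	1898399	+	CHG	10.45	0.333	0.148	0.222	0.200
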