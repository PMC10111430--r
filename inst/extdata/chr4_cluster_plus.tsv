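site	dataset	ratio	meth_reads	unmeth_reads	ci_lower
2524758	WT1	0	0	14	0
2524758	WT2	0	0	75	0
2524758	WT3	0	0	34	0
2524758	KO	0	0	32	0
2524758	BSP-V	0	NA	NA	NA
2524758	BSP-D	0.027	NA	NA	NA
2524760	WT1	0	0	14	0
2524760	WT2	0.013	1	74	0.002
2524760	WT3	0.059	2	32	0.016
2524760	KO	0	0	32	0
2524760	BSP-V	0	NA	NA	NA
2524760	BSP-D	0.054	NA	NA	NA
2524803	WT1	0.308	4	9	0.127
2524803	WT2	0.306	19	43	0.206
2524803	WT3	0.438	14	18	0.282
2524803	KO	0.480	12	13	0.300
2524803	BSP-V	0.152	NA	NA	NA
2524803	BSP-D	0.162	NA	NA	NA
2524813	WT1	0	0	13	0
2524813	WT2	0.018	1	55	0.003
2524813	WT3	0	0	34	0
2524813	KO	0	0	25	0
2524813	BSP-V	0	NA	NA	NA
2524813	BSP-D	0.054	NA	NA	NA
2524847	WT1	0.2873	3	8	0.097
2524847	WT2	0.073	4	51	0.029
2524847	WT3	0.067	2	28	0.018
2524847	KO	0.143	3	18	0.050
2524847	BSP-V	0.061	NA	NA	NA
2524847	BSP-D	0.027	NA	NA	NA
2524849	WT1	0	0	11	0
2524849	WT2	0.019	1	54	0.003
2524849	WT3	0	0	30	0
2524849	KO	0.045	1	22	0.008
2524849	BSP-V	0.030	NA	NA	NA
2524849	BSP-D	0.027	NA	NA	NA
2524850	WT1	0	0	11	0
2524850	WT2	0	0	53	0
2524850	WT3	0	0	30	0
2524850	KO	0.095	2	19	0.027
2524850	BSP-V	0.061	NA	NA	NA
2524850	BSP-D	0	NA	NA	NA
2525008	WT1	NA	NA	NA	NA
2525008	WT2	0	0	34	0
2525008	WT3	0	0	8	0
2525008	KO	0	0	9	0
2525008	BSP-V	0.030	NA	NA	NA
2525008	BSP-D	0.081	NA	NA	NA
2525071	WT1	NA	NA	NA	NA
2525071	WT2	0.026	1	38	0.005
2525071	WT3	0	0	13	0
2525071	KO	0	0	13	0
2525071	BSP-V	0.030	NA	NA	NA
2525071	BSP-D	0.027	NA	NA	NA
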