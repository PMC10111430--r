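site	dataset	ratio	meth_reads	unmeth_reads	ci_lower
2524729	WT1	0.043	1	22	0
2524729	WT2	0	0	79	0
2524729	WT3	0	0	31	0
2524729	KO	0	0	35	0
2524729	BSP-V	0.029	NA	NA	NA
2524729	BSP-D	0	NA	NA	NA
2524741	WT1	0	0	25	0
2524741	WT2	0.012	1	80	0.002
2524741	WT3	0.061	2	31	0.017
2524741	KO	0	0	36	0
2524741	BSP-V	0	NA	NA	NA
2524741	BSP-D	0.028	NA	NA	NA
2524753	WT1	0	0	28	0
2524753	WT2	0	0	76	0
2524753	WT3	0.031	1	31	0.006
2524753	KO	0.027	1	36	0.005
2524753	BSP-V	0	NA	NA	NA
2524753	BSP-D	0.028	NA	NA	NA
2524780	WT1	0	0	29	0
2524780	WT2	0.081	6	68	0.038
2524780	WT3	0.036	1	27	0.006
2524780	KO	0.108	4	33	0.043
2524780	BSP-V	0	NA	NA	NA
2524780	BSP-D	0.056	NA	NA	NA
2524824	WT1	0.143	3	18	0.050
2524824	WT2	0.345	23	45	0.242
2524824	WT3	0.318	7	15	0.164
2524824	KO	0.375	12	20	0.229
2524824	BSP-V	0.118	NA	NA	NA
2524824	BSP-D	0.083	NA	NA	NA
2524889	WT1	0.067	1	14	0.012
2524889	WT2	0.017	1	58	0.003
2524889	WT3	0	0	25	0
2524889	KO	0	0	28	0
2524889	BSP-V	0.029	NA	NA	NA
2524889	BSP-D	0	NA	NA	NA
2524976	WT1	0	0	5	0
2524976	WT2	0	0	38	0
2524976	WT3	0.059	1	16	0.010
2524976	KO	0	0	13	0
2524976	BSP-V	0.029	NA	NA	NA
2524976	BSP-D	0.028	NA	NA	NA
2525007	WT1	0	0	6	0
2525007	WT2	0	0	30	0
2525007	WT3	0	0	7	0
2525007	KO	0	0	8	0
2525007	BSP-V	0.029	NA	NA	NA
2525007	BSP-D	0	NA	NA	NA
2525038	WT1	0	0	6	0
2525038	WT2	0.059	2	34	0.016
2525038	WT3	0	0	9	0
2525038	KO	0	0	10	0
2525038	BSP-V	0	NA	NA	NA
2525038	BSP-D	0.028	NA	NA	NA
2525039	WT1	0	0	6	0
2525039	WT2	0	0	36	0
2525039	WT3	0	0	9	0
2525039	KO	0	0	10	0
2525039	BSP-V	0	NA	NA	NA
2525039	BSP-D	0.028	NA	NA	NA
2525049	WT1	0	0	6	0
2525049	WT2	0.029	1	38	0.005
2525049	WT3	0	0	9	0
2525049	KO	0	0	11	0
2525049	BSP-V	0.029	NA	NA	NA
2525049	BSP-D	0	NA	NA	NA
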