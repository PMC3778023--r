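id	kind	resolution	parent	locus	or	ci_low	ci_high	control_freq	n_cases	n_controls	exposure_prev	applies_to	in_wtccc	in_ukragg
*01	hla_allele	two_digit	NA	HLA-DRB1	1.30	1.21	1.40	0.113	NA	NA	NA	all	TRUE	TRUE
*03	hla_allele	two_digit	NA	HLA-DRB1	0.59	0.54	0.64	0.128	NA	NA	NA	all	TRUE	TRUE
*04	hla_allele	two_digit	NA	HLA-DRB1	3.71	3.49	3.93	0.174	NA	NA	NA	all	TRUE	TRUE
*07	hla_allele	two_digit	NA	HLA-DRB1	0.49	0.45	0.54	0.133	NA	NA	NA	all	TRUE	TRUE
*08	hla_allele	two_digit	NA	HLA-DRB1	0.41	0.34	0.50	0.029	NA	NA	NA	all	TRUE	TRUE
*10	hla_allele	two_digit	NA	HLA-DRB1	2.53	2.04	3.14	0.008	NA	NA	NA	all	TRUE	TRUE
*11	hla_allele	two_digit	NA	HLA-DRB1	0.48	0.43	0.54	0.094	NA	NA	NA	all	TRUE	TRUE
*13	hla_allele	two_digit	NA	HLA-DRB1	0.33	0.30	0.37	0.114	NA	NA	NA	all	TRUE	TRUE
*14	hla_allele	two_digit	NA	HLA-DRB1	0.50	0.40	0.62	0.025	NA	NA	NA	all	TRUE	TRUE
*15	hla_allele	two_digit	NA	HLA-DRB1	0.59	0.54	0.64	0.142	NA	NA	NA	all	TRUE	TRUE
*01:01	hla_allele	four_digit	*01	HLA-DRB1	1.38	1.28	1.50	0.097	NA	NA	NA	all	TRUE	TRUE
*03:01	hla_allele	four_digit	*03	HLA-DRB1	0.59	0.54	0.64	0.128	NA	NA	NA	all	TRUE	TRUE
*04:01	hla_allele	four_digit	*04	HLA-DRB1	4.14	3.86	4.44	0.104	NA	NA	NA	all	TRUE	TRUE
*04:04	hla_allele	four_digit	*04	HLA-DRB1	3.17	2.83	3.54	0.036	NA	NA	NA	all	TRUE	TRUE
*04:05	hla_allele	four_digit	*04	HLA-DRB1	2.31	1.77	3.01	0.007	NA	NA	NA	all	TRUE	TRUE
*04:08	hla_allele	four_digit	*04	HLA-DRB1	5.48	4.11	7.30	0.005	NA	NA	NA	all	TRUE	TRUE
*07:01	hla_allele	four_digit	*07	HLA-DRB1	0.49	0.45	0.54	0.133	NA	NA	NA	all	TRUE	TRUE
*08:01	hla_allele	four_digit	*08	HLA-DRB1	0.34	0.26	0.44	0.019	NA	NA	NA	all	TRUE	TRUE
*10:01	hla_allele	four_digit	*10	HLA-DRB1	2.53	2.04	3.14	0.008	NA	NA	NA	all	TRUE	TRUE
*11:01	hla_allele	four_digit	*11	HLA-DRB1	0.44	0.38	0.52	0.061	NA	NA	NA	all	TRUE	TRUE
*11:04	hla_allele	four_digit	*11	HLA-DRB1	0.15	0.10	0.23	0.024	NA	NA	NA	all	TRUE	TRUE
*13:01	hla_allele	four_digit	*13	HLA-DRB1	0.28	0.24	0.33	0.061	NA	NA	NA	all	TRUE	TRUE
*13:02	hla_allele	four_digit	*13	HLA-DRB1	0.29	0.23	0.38	0.027	NA	NA	NA	all	TRUE	TRUE
*14:01	hla_allele	four_digit	*14	HLA-DRB1	0.46	0.36	0.59	0.022	NA	NA	NA	all	TRUE	TRUE
*15:01	hla_allele	four_digit	*15	HLA-DRB1	0.57	0.53	0.62	0.136	NA	NA	NA	all	TRUE	TRUE
rs2476601	snp	not_applicable	NA	PTPN22	1.94	1.81	2.08	0.10	NA	NA	NA	all	TRUE	TRUE
rs6920220	snp	not_applicable	NA	TNFAIP3	1.22	1.16	1.29	0.22	NA	NA	NA	all	TRUE	TRUE
rs6859219	snp	not_applicable	NA	ANKRD55-IL6ST	0.78	0.72	0.85	0.21	NA	NA	NA	all	TRUE	FALSE
rs4810485	snp	not_applicable	NA	CD40	0.85	0.80	0.90	0.25	NA	NA	NA	all	TRUE	TRUE
rs3087243	snp	not_applicable	NA	CTLA4	0.87	0.83	0.91	0.44	NA	NA	NA	all	TRUE	TRUE
rs5029937	snp	not_applicable	NA	TNFAIP3	1.40	1.24	1.58	0.04	NA	NA	NA	all	TRUE	TRUE
rs706778	snp	not_applicable	NA	IL2RA	1.14	1.09	1.20	0.40	NA	NA	NA	all	TRUE	TRUE
rs874040	snp	not_applicable	NA	RBPJ	1.14	1.08	1.20	0.30	NA	NA	NA	all	FALSE	TRUE
rs3761847	snp	not_applicable	NA	TRAF1-C5	1.13	1.08	1.18	0.43	NA	NA	NA	all	TRUE	TRUE
rs7574865	snp	not_applicable	NA	STAT4	1.16	1.10	1.23	0.22	NA	NA	NA	all	TRUE	TRUE
rs934734	snp	not_applicable	NA	SPRED2	1.13	1.08	1.19	0.49	NA	NA	NA	all	TRUE	FALSE
rs3093023	snp	not_applicable	NA	CCR6	1.13	1.08	1.19	0.43	NA	NA	NA	all	TRUE	TRUE
rs13315591	snp	not_applicable	NA	PXK	1.29	1.17	1.43	0.09	NA	NA	NA	all	TRUE	TRUE
rs26232	snp	not_applicable	NA	C5orf30	0.88	0.84	0.93	0.32	NA	NA	NA	all	TRUE	TRUE
rs951005	snp	not_applicable	NA	CCL21	0.84	0.78	0.90	0.16	NA	NA	NA	all	FALSE	TRUE
rs13031237	snp	not_applicable	NA	REL	1.13	1.07	1.18	0.37	NA	NA	NA	all	TRUE	TRUE
rs10865035	snp	not_applicable	NA	AFF3	1.12	1.07	1.17	0.47	NA	NA	NA	all	TRUE	TRUE
rs4750316	snp	not_applicable	NA	PRKCQ	0.87	0.82	0.92	0.19	NA	NA	NA	all	TRUE	TRUE
rs10488631	snp	not_applicable	NA	IRF5	1.19	1.10	1.28	0.11	NA	NA	NA	all	TRUE	FALSE
rs3890745	snp	not_applicable	NA	TNFRSF14	0.89	0.85	0.94	0.32	NA	NA	NA	all	TRUE	TRUE
rs11586238	snp	not_applicable	NA	CD2-CD58	1.13	1.07	1.19	0.24	NA	NA	NA	all	TRUE	TRUE
rs2736340	snp	not_applicable	NA	BLK	1.12	1.07	1.18	0.25	NA	NA	NA	all	TRUE	TRUE
rs1980422	snp	not_applicable	NA	CD28	1.12	1.06	1.18	0.24	NA	NA	NA	all	TRUE	TRUE
rs548234	snp	not_applicable	NA	PRDM1	1.10	1.05	1.16	0.33	NA	NA	NA	all	TRUE	TRUE
rs2812378	snp	not_applicable	NA	CCL21	1.10	1.05	1.16	0.34	NA	NA	NA	all	TRUE	TRUE
rs10919563	snp	not_applicable	NA	PTPRC	0.88	0.82	0.94	0.13	NA	NA	NA	all	TRUE	TRUE
rs1678542	snp	not_applicable	NA	KIF5A-PIP4K2C	0.91	0.87	0.96	0.38	NA	NA	NA	all	TRUE	TRUE
rs540386	snp	not_applicable	NA	TRAF6	0.88	0.83	0.94	0.14	NA	NA	NA	all	TRUE	TRUE
rs12746613	snp	not_applicable	NA	FCGR2A	1.13	1.06	1.21	0.12	NA	NA	NA	all	TRUE	TRUE
rs394581	snp	not_applicable	NA	TAGAP	0.91	0.87	0.96	0.30	NA	NA	NA	all	TRUE	TRUE
rs10499194	snp	not_applicable	NA	TNFAIP3	0.91	0.87	0.96	0.27	NA	NA	NA	all	TRUE	TRUE
rs6822844	snp	not_applicable	NA	IL2-IL21	0.90	0.84	0.95	0.18	NA	NA	NA	all	FALSE	TRUE
rs2104286	snp	not_applicable	NA	IL2RA	0.92	0.87	0.97	0.27	NA	NA	NA	all	TRUE	TRUE
rs3218253	snp	not_applicable	NA	IL2RB	1.09	1.03	1.15	0.26	NA	NA	NA	all	TRUE	TRUE
ever_smoking	environmental	not_applicable	NA	NA	3.02	2.35	3.88	NA	NA	NA	0.57	males	TRUE	TRUE
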