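probe_index	symbol	fold_rm_hn	probability_score	t_p_value	fold_rm_pm	prior_study
ps001	ATF3	5.72	1.52E-07	1.22E-06	3.39	TRUE
ps002	FOS	4.62	1.23E-04	2.69E-05	2.81	TRUE
ps003	FOSB	4.32	6.33E-04	7.99E-05	1.76	TRUE
ps004	NR4A2	4.02	5.80E-07	4.57E-07	3.21	TRUE
ps005	HIST1H2BG	3.99	5.15E-04	1.99E-01	4.40	FALSE
ps006	CDH19	3.94	2.45E-04	1.73E-02	1.66	TRUE
ps007	HIST1H2BB	3.85	7.53E-09	2.43E-08	4.21	TRUE
ps008	NR4A2	3.83	2.76E-06	1.09E-05	3.43	TRUE
ps009	IER2	3.77	1.08E-08	1.82E-08	3.52	TRUE
ps010	BTG2	3.69	3.04E-07	2.15E-06	3.92	TRUE
ps011	NA	3.68	1.37E-05	1.62E-05	4.57	TRUE
ps012	NR4A2	3.46	6.02E-07	1.34E-06	3.33	TRUE
ps013	EIF1	3.27	1.18E-07	5.47E-07	2.92	TRUE
ps014	JUN	3.26	1.32E-08	6.70E-09	1.87	TRUE
ps015	ZFAND5	3.10	2.37E-05	1.21E-03	4.03	FALSE
ps016	NA	2.92	3.15E-05	2.44E-04	2.13	TRUE
ps017	DUSP1	2.87	1.07E-05	4.37E-06	2.17	TRUE
ps018	NR4A3	2.85	3.72E-06	3.48E-05	3.07	TRUE
ps019	CD69	2.84	1.38E-04	8.07E-04	4.85	TRUE
ps020	SPRY1	2.70	3.26E-04	2.37E-03	3.19	FALSE
ps021	IL6	2.66	5.84E-04	7.09E-03	2.56	FALSE
ps022	PTP4A1	2.65	2.12E-07	1.01E-06	2.69	TRUE
ps023	TRIM37	2.60	3.61E-04	3.88E-03	3.63	FALSE
ps024	RGS2	2.60	1.24E-03	1.28E-03	1.37	TRUE
ps025	KLF4	2.59	2.54E-04	6.69E-04	1.56	TRUE
ps026	CX3CR1	2.58	1.69E-04	2.14E-02	2.65	FALSE
ps027	NR4A1	2.56	4.63E-04	7.42E-04	1.98	TRUE
ps028	H3F3B	2.53	1.04E-07	7.24E-08	1.93	TRUE
ps029	DUSP2	2.53	4.35E-04	4.81E-03	1.25	TRUE
ps030	TXNIP	2.50	3.17E-04	5.90E-04	2.96	FALSE
ps031	PTGS2	2.47	7.16E-04	3.11E-03	1.87	TRUE
ps032	EGR1	2.47	3.83E-04	2.34E-04	3.64	TRUE
ps033	SNF1LK	2.37	2.84E-05	4.52E-05	2.55	TRUE
ps034	EGR1	2.37	7.45E-05	4.98E-05	2.63	TRUE
ps035	PTP4A1	2.34	2.92E-05	7.13E-04	2.62	TRUE
ps036	CD93	2.33	2.54E-04	4.60E-03	2.58	FALSE
ps037	MAFF	2.31	5.29E-04	1.04E-03	2.86	FALSE
ps038	SAV1	2.29	6.26E-04	1.00E-02	2.94	FALSE
ps039	EIF4A1	2.28	2.92E-06	9.00E-06	2.38	TRUE
ps040	JUN	2.25	3.43E-08	7.17E-08	3.39	TRUE
ps041	ZFP36	2.23	1.29E-04	4.28E-04	2.04	TRUE
ps042	RGS5	2.23	1.34E-03	1.97E-03	2.49	FALSE
ps043	YWHAZ	2.22	5.60E-04	4.32E-03	1.93	TRUE
ps044	PNMAL1	2.20	1.05E-03	1.18E-02	1.88	FALSE
ps045	JUN	2.19	2.34E-05	1.20E-05	2.13	TRUE
ps046	MCL1	2.17	5.52E-05	3.24E-04	2.47	TRUE
ps047	FRZB	2.15	1.36E-03	2.02E-02	2.44	FALSE
ps048	ITGBL1	2.15	1.67E-03	2.23E-02	1.85	FALSE
ps049	ABLIM1	2.13	7.96E-05	1.29E-04	2.07	FALSE
ps050	NEDD4L	2.11	8.35E-05	1.15E-04	2.13	FALSE
ps051	ARL4C	2.11	4.00E-05	3.43E-04	1.83	FALSE
ps052	AQP3	2.11	1.46E-03	1.01E-02	2.15	FALSE
ps053	AHNAK	2.11	2.59E-04	1.54E-03	1.74	FALSE
ps054	LEPROT	2.10	1.05E-03	1.93E-03	3.10	FALSE
ps055	MCL1	2.10	2.20E-04	6.17E-04	1.98	FALSE
ps056	CHN1	2.10	9.45E-04	5.86E-03	1.67	FALSE
ps057	SEMA5A	2.10	6.21E-04	4.38E-03	1.86	FALSE
ps058	RGS5	2.10	1.02E-03	3.52E-03	2.75	FALSE
ps059	IER3	2.09	3.00E-04	6.81E-04	1.76	FALSE
ps060	TIMM23	2.08	8.16E-06	1.41E-05	2.29	FALSE
ps061	NSF	2.08	5.52E-04	7.69E-03	2.50	FALSE
ps062	PTP4A1	2.08	6.24E-04	3.98E-03	1.81	TRUE
ps063	FHL1	2.08	1.50E-03	3.17E-02	1.46	FALSE
ps064	BAG5	2.08	6.01E-04	6.49E-03	2.29	FALSE
ps065	EIF5	2.05	5.40E-05	4.01E-04	1.97	TRUE
ps066	NIPBL	2.04	1.01E-04	3.74E-04	1.74	FALSE
ps067	GMPPA	0.48	6.45E-04	8.71E-03	0.58	FALSE
ps068	TRO	0.48	1.27E-03	8.30E-04	0.37	TRUE
ps069	GNB2	0.48	2.13E-04	1.04E-03	0.49	FALSE
ps070	CST3	0.47	1.49E-03	7.13E-03	0.41	FALSE
ps071	PDXDC2	0.47	8.07E-04	2.90E-03	0.35	FALSE
ps072	ZYX	0.47	3.92E-04	7.60E-04	0.38	FALSE
ps073	UBA1	0.47	1.32E-03	3.54E-03	0.41	FALSE
ps074	MARCKS	0.47	1.41E-03	2.02E-02	0.35	FALSE
ps075	RARA	0.46	3.51E-04	5.48E-04	0.47	FALSE
ps076	PELP1	0.46	2.85E-05	8.64E-05	0.48	FALSE
ps077	PRDX2	0.46	1.32E-03	6.95E-04	0.41	FALSE
ps078	RPL28	0.45	1.35E-04	1.47E-04	0.42	FALSE
ps079	COL16A1	0.44	1.41E-03	9.05E-04	0.40	FALSE
ps080	BAT2	0.44	4.61E-04	1.46E-02	0.45	FALSE
ps081	PLTP	0.44	5.35E-04	1.65E-03	0.39	FALSE
ps082	CLU	0.44	2.13E-04	5.33E-04	0.52	FALSE
ps083	PIB5PA	0.43	3.66E-04	1.21E-04	0.35	FALSE
ps084	TNC	0.42	4.90E-04	6.46E-03	0.56	FALSE
ps085	IFI6	0.42	2.74E-04	5.88E-03	0.65	FALSE
ps086	INTS3	0.42	6.59E-04	9.70E-04	0.46	FALSE
ps087	H2AFX	0.42	2.56E-04	4.63E-04	0.41	FALSE
ps088	FLJ11292	0.42	9.81E-04	1.83E-01	0.71	FALSE
ps089	RPS26	0.42	9.31E-04	1.40E-03	0.36	FALSE
ps090	IFI35	0.40	7.07E-04	4.10E-04	0.43	FALSE
ps091	ZFP36L2	0.40	1.38E-03	5.99E-02	0.45	FALSE
ps092	C17orf101	0.38	3.20E-04	4.73E-04	0.39	FALSE
ps093	LRRC14	0.37	1.08E-03	9.10E-04	0.32	FALSE
ps094	NPIPL3	0.34	1.10E-03	3.59E-03	0.78	FALSE
ps095	BST2	0.31	9.68E-05	9.65E-03	0.33	FALSE
ps096	SEC14L1	0.30	4.14E-05	6.00E-03	0.42	FALSE
ps097	CALD1	0.27	7.01E-06	5.90E-05	0.21	FALSE
ps098	CSN2	0.10	9.09E-05	1.52E-01	1.30	FALSE
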