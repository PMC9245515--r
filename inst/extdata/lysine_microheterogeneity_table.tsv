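# Quantitative micro-heterogenic occupancy (%) of O-glycosylated lysine
# sites in collagen I chains from zebrafish cardiac ECM during
# regeneration, transcribed from the published microheterogeneity table
# (mean +/- SEM over biological replicates). States: unmod = unmodified
# lysine, HyK = hydroxylysine, G-HyK = galactosyl-hydroxylysine,
# GG-HyK = glucosylgalactosyl-hydroxylysine (the source table prints GK /
# GGK for two rows; normalized here). ND (not detected) rows carry NA.
# The GG-HyK increase at COL1A1a K1017 at 30 DPA is the one ANOVA-
# significant change (significant = yes).
chain_id	site	state	condition	mean	sem	significant
COL1A1a	261	unmod	sham	36.62	9.7	no
COL1A1a	261	unmod	7DPA	43.75	4.38	no
COL1A1a	261	unmod	14DPA	46.09	4.89	no
COL1A1a	261	unmod	30DPA	32.30	5.08	no
COL1A1a	261	HyK	sham	38.38	10.38	no
COL1A1a	261	HyK	7DPA	34.81	12.3	no
COL1A1a	261	HyK	14DPA	21.13	2.85	no
COL1A1a	261	HyK	30DPA	45.72	8.65	no
COL1A1a	261	G-HyK	sham	16.71	4.9	no
COL1A1a	261	G-HyK	7DPA	17.85	12.0	no
COL1A1a	261	G-HyK	14DPA	31.26	3.01	no
COL1A1a	261	G-HyK	30DPA	20.22	3.01	no
COL1A1a	261	GG-HyK	sham	8.28	6.5	no
COL1A1a	261	GG-HyK	7DPA	3.59	4.3	no
COL1A1a	261	GG-HyK	14DPA	1.32	0.97	no
COL1A1a	261	GG-HyK	30DPA	2.35	0.57	no
COL1A1a	270	unmod	sham	50.46	5.3	no
COL1A1a	270	unmod	7DPA	32.92	4.4	no
COL1A1a	270	unmod	14DPA	26.58	1.7	no
COL1A1a	270	unmod	30DPA	46.48	4.1	no
COL1A1a	270	HyK	sham	34.97	0.7	no
COL1A1a	270	HyK	7DPA	37.13	1.3	no
COL1A1a	270	HyK	14DPA	46.12	1.1	no
COL1A1a	270	HyK	30DPA	40.69	4.4	no
COL1A1a	270	G-HyK	sham	12.26	5.0	no
COL1A1a	270	G-HyK	7DPA	29.03	4.4	no
COL1A1a	270	G-HyK	14DPA	24.56	2.7	no
COL1A1a	270	G-HyK	30DPA	11.52	0.4	no
COL1A1a	270	GG-HyK	sham	2.32	1.1	no
COL1A1a	270	GG-HyK	7DPA	0.93	1.3	no
COL1A1a	270	GG-HyK	14DPA	2.74	0.2	no
COL1A1a	270	GG-HyK	30DPA	1.30	0.7	no
COL1A1a	504	unmod	sham	35.12	0.2	no
COL1A1a	504	unmod	7DPA	6.54	0.3	no
COL1A1a	504	unmod	14DPA	34.96	46.9	no
COL1A1a	504	unmod	30DPA	51.61	20.2	no
COL1A1a	504	HyK	sham	7.20	4.4	no
COL1A1a	504	HyK	7DPA	3.49	0.3	no
COL1A1a	504	HyK	14DPA	16.03	22.4	no
COL1A1a	504	HyK	30DPA	16.85	5.2	no
COL1A1a	504	G-HyK	sham	57.68	4.2	no
COL1A1a	504	G-HyK	7DPA	89.97	0.0	no
COL1A1a	504	G-HyK	14DPA	49.01	69.3	no
COL1A1a	504	G-HyK	30DPA	31.54	15.0	no
COL1A1a	504	GG-HyK	sham	NA	NA	no
COL1A1a	504	GG-HyK	7DPA	NA	NA	no
COL1A1a	504	GG-HyK	14DPA	NA	NA	no
COL1A1a	504	GG-HyK	30DPA	NA	NA	no
COL1A1a	570	unmod	sham	59.52	12.5	no
COL1A1a	570	unmod	7DPA	24.79	15.4	no
COL1A1a	570	unmod	14DPA	17.67	1.6	no
COL1A1a	570	unmod	30DPA	42.84	51.5	no
COL1A1a	570	HyK	sham	14.06	4.6	no
COL1A1a	570	HyK	7DPA	6.83	7.6	no
COL1A1a	570	HyK	14DPA	4.50	0.1	no
COL1A1a	570	HyK	30DPA	0.21	0.3	no
COL1A1a	570	G-HyK	sham	NA	NA	no
COL1A1a	570	G-HyK	7DPA	NA	NA	no
COL1A1a	570	G-HyK	14DPA	NA	NA	no
COL1A1a	570	G-HyK	30DPA	NA	NA	no
COL1A1a	570	GG-HyK	sham	26.42	17.1	no
COL1A1a	570	GG-HyK	7DPA	68.39	7.8	no
COL1A1a	570	GG-HyK	14DPA	77.83	1.6	no
COL1A1a	570	GG-HyK	30DPA	56.95	51.8	no
COL1A1a	693	unmod	sham	16.05	1.8	no
COL1A1a	693	unmod	7DPA	11.35	1.4	no
COL1A1a	693	unmod	14DPA	21.14	15.4	no
COL1A1a	693	unmod	30DPA	17.46	2.3	no
COL1A1a	693	HyK	sham	73.86	2.2	no
COL1A1a	693	HyK	7DPA	83.40	0.1	no
COL1A1a	693	HyK	14DPA	70.60	23.8	no
COL1A1a	693	HyK	30DPA	74.25	1.7	no
COL1A1a	693	G-HyK	sham	1.34	0.3	no
COL1A1a	693	G-HyK	7DPA	0.25	0.4	no
COL1A1a	693	G-HyK	14DPA	0.56	0.8	no
COL1A1a	693	G-HyK	30DPA	1.47	0.2	no
COL1A1a	693	GG-HyK	sham	8.75	0.4	no
COL1A1a	693	GG-HyK	7DPA	5.00	1.0	no
COL1A1a	693	GG-HyK	14DPA	7.69	9.2	no
COL1A1a	693	GG-HyK	30DPA	6.82	3.8	no
COL1A1a	846	unmod	sham	NA	NA	no
COL1A1a	846	unmod	7DPA	NA	NA	no
COL1A1a	846	unmod	14DPA	NA	NA	no
COL1A1a	846	unmod	30DPA	NA	NA	no
COL1A1a	846	HyK	sham	NA	NA	no
COL1A1a	846	HyK	7DPA	NA	NA	no
COL1A1a	846	HyK	14DPA	NA	NA	no
COL1A1a	846	HyK	30DPA	NA	NA	no
COL1A1a	846	G-HyK	sham	48.69	29.7	no
COL1A1a	846	G-HyK	7DPA	85.04	19.4	no
COL1A1a	846	G-HyK	14DPA	51.02	9.0	no
COL1A1a	846	G-HyK	30DPA	68.87	5.5	no
COL1A1a	846	GG-HyK	sham	51.31	29.7	no
COL1A1a	846	GG-HyK	7DPA	14.96	19.4	no
COL1A1a	846	GG-HyK	14DPA	48.98	9.0	no
COL1A1a	846	GG-HyK	30DPA	31.13	5.5	no
COL1A1a	1017	unmod	sham	62.44	0.3	no
COL1A1a	1017	unmod	7DPA	33.69	22.8	no
COL1A1a	1017	unmod	14DPA	52.55	21.8	no
COL1A1a	1017	unmod	30DPA	60.09	0.5	no
COL1A1a	1017	HyK	sham	34.82	0.4	no
COL1A1a	1017	HyK	7DPA	62.96	20.9	no
COL1A1a	1017	HyK	14DPA	36.95	22.1	no
COL1A1a	1017	HyK	30DPA	24.44	0.2	no
COL1A1a	1017	G-HyK	sham	NA	NA	no
COL1A1a	1017	G-HyK	7DPA	NA	NA	no
COL1A1a	1017	G-HyK	14DPA	NA	NA	no
COL1A1a	1017	G-HyK	30DPA	NA	NA	no
COL1A1a	1017	GG-HyK	sham	2.74	0.7	no
COL1A1a	1017	GG-HyK	7DPA	3.35	1.9	no
COL1A1a	1017	GG-HyK	14DPA	10.50	0.3	no
COL1A1a	1017	GG-HyK	30DPA	15.47	0.3	yes
COL1A1b	264	unmod	sham	50.52	15.5	no
COL1A1b	264	unmod	7DPA	40.63	50.7	no
COL1A1b	264	unmod	14DPA	52.94	15.8	no
COL1A1b	264	unmod	30DPA	20.39	20.2	no
COL1A1b	264	HyK	sham	41.23	8.2	no
COL1A1b	264	HyK	7DPA	53.16	56.0	no
COL1A1b	264	HyK	14DPA	30.76	34.6	no
COL1A1b	264	HyK	30DPA	46.65	44.7	no
COL1A1b	264	G-HyK	sham	5.19	4.4	no
COL1A1b	264	G-HyK	7DPA	4.64	3.6	no
COL1A1b	264	G-HyK	14DPA	9.75	10.8	no
COL1A1b	264	G-HyK	30DPA	27.51	20.7	no
COL1A1b	264	GG-HyK	sham	3.05	2.9	no
COL1A1b	264	GG-HyK	7DPA	1.57	1.6	no
COL1A1b	264	GG-HyK	14DPA	6.54	7.9	no
COL1A1b	264	GG-HyK	30DPA	5.45	3.7	no
COL1A1b	273	unmod	sham	NA	NA	no
COL1A1b	273	unmod	7DPA	NA	NA	no
COL1A1b	273	unmod	14DPA	NA	NA	no
COL1A1b	273	unmod	30DPA	NA	NA	no
COL1A1b	273	HyK	sham	41.65	47.5	no
COL1A1b	273	HyK	7DPA	50.93	39.7	no
COL1A1b	273	HyK	14DPA	24.43	25.6	no
COL1A1b	273	HyK	30DPA	33.90	36.0	no
COL1A1b	273	G-HyK	sham	5.58	4.6	no
COL1A1b	273	G-HyK	7DPA	33.38	20.8	no
COL1A1b	273	G-HyK	14DPA	27.55	13.3	no
COL1A1b	273	G-HyK	30DPA	19.99	10.5	no
COL1A1b	273	GG-HyK	sham	52.77	42.9	no
COL1A1b	273	GG-HyK	7DPA	15.69	19.0	no
COL1A1b	273	GG-HyK	14DPA	48.02	38.9	no
COL1A1b	273	GG-HyK	30DPA	46.11	25.5	no
COL1A1b	849	unmod	sham	27.06	1.1	no
COL1A1b	849	unmod	7DPA	10.35	13.7	no
COL1A1b	849	unmod	14DPA	11.17	2.2	no
COL1A1b	849	unmod	30DPA	22.95	3.4	no
COL1A1b	849	HyK	sham	67.46	1.1	no
COL1A1b	849	HyK	7DPA	68.53	16.8	no
COL1A1b	849	HyK	14DPA	70.77	9.7	no
COL1A1b	849	HyK	30DPA	62.89	0.3	no
COL1A1b	849	G-HyK	sham	3.35	0.4	no
COL1A1b	849	G-HyK	7DPA	6.76	9.4	no
COL1A1b	849	G-HyK	14DPA	12.97	4.5	no
COL1A1b	849	G-HyK	30DPA	9.48	1.5	no
COL1A1b	849	GG-HyK	sham	2.13	0.4	no
COL1A1b	849	GG-HyK	7DPA	14.36	12.4	no
COL1A1b	849	GG-HyK	14DPA	5.09	2.9	no
COL1A1b	849	GG-HyK	30DPA	4.68	2.2	no
COL1A2	254	unmod	sham	6.48	3.2	no
COL1A2	254	unmod	7DPA	20.75	14.6	no
COL1A2	254	unmod	14DPA	21.61	14.3	no
COL1A2	254	unmod	30DPA	55.69	18.4	no
COL1A2	254	HyK	sham	89.24	1.6	no
COL1A2	254	HyK	7DPA	78.24	13.4	no
COL1A2	254	HyK	14DPA	69.76	2.2	no
COL1A2	254	HyK	30DPA	43.90	18.1	no
COL1A2	254	G-HyK	sham	0.11	0.0	no
COL1A2	254	G-HyK	7DPA	0.10	0.1	no
COL1A2	254	G-HyK	14DPA	0.22	0.3	no
COL1A2	254	G-HyK	30DPA	0.05	0.0	no
COL1A2	254	GG-HyK	sham	4.17	4.8	no
COL1A2	254	GG-HyK	7DPA	0.91	1.1	no
COL1A2	254	GG-HyK	14DPA	8.40	11.7	no
COL1A2	254	GG-HyK	30DPA	0.36	0.3	no
COL1A2	644	unmod	sham	NA	NA	no
COL1A2	644	unmod	7DPA	NA	NA	no
COL1A2	644	unmod	14DPA	NA	NA	no
COL1A2	644	unmod	30DPA	NA	NA	no
COL1A2	644	HyK	sham	84.59	1.8	no
COL1A2	644	HyK	7DPA	61.15	40.2	no
COL1A2	644	HyK	14DPA	95.15	6.5	no
COL1A2	644	HyK	30DPA	90.77	11.1	no
COL1A2	644	G-HyK	sham	NA	NA	no
COL1A2	644	G-HyK	7DPA	NA	NA	no
COL1A2	644	G-HyK	14DPA	NA	NA	no
COL1A2	644	G-HyK	30DPA	NA	NA	no
COL1A2	644	GG-HyK	sham	15.41	1.8	no
COL1A2	644	GG-HyK	7DPA	38.85	40.2	no
COL1A2	644	GG-HyK	14DPA	4.85	6.5	no
COL1A2	644	GG-HyK	30DPA	9.23	11.1	no
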