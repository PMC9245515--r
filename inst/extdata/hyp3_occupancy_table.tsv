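# Quantitative 3-hydroxyproline site occupancy (%) in collagen I chains
# and one COL5A2a cluster from zebrafish cardiac ECM during regeneration,
# transcribed from the published occupancy table (mean +/- SD over
# biological replicates; none of the rows reached ANOVA significance).
# The COL5A2a row is a two-site cluster quantified jointly.
chain_id	site	condition	mean	sd
COL1A1a	707	sham	7.55	4.3
COL1A1a	707	7DPA	31.49	38.1
COL1A1a	707	14DPA	21.21	7.8
COL1A1a	707	30DPA	20.50	1.5
COL1A1a	869	sham	35.37	6.9
COL1A1a	869	7DPA	22.82	13.3
COL1A1a	869	14DPA	48.10	63.8
COL1A1a	869	30DPA	20.12	2.9
COL1A1a	878	sham	28.87	7.2
COL1A1a	878	7DPA	17.57	18.4
COL1A1a	878	14DPA	27.63	35.8
COL1A1a	878	30DPA	12.76	1.8
COL1A1a	1148	sham	48.73	14.7
COL1A1a	1148	7DPA	44.03	17.0
COL1A1a	1148	14DPA	68.96	41.1
COL1A1a	1148	30DPA	7.23	4.6
COL5A2a	1195,1201	sham	1.77	1.3
COL5A2a	1195,1201	7DPA	23.97	4.5
COL5A2a	1195,1201	14DPA	55.24	47.4
COL5A2a	1195,1201	30DPA	30.04	41.1
COL1A2	718	sham	0.19	0.1
COL1A2	718	7DPA	0.20	0.3
COL1A2	718	14DPA	0.10	0.1
COL1A2	718	30DPA	10.54	7.4
COL1A2	925	sham	5.14	5.7
COL1A2	925	7DPA	10.00	13.2
COL1A2	925	14DPA	0.53	0.7
COL1A2	925	30DPA	1.86	1.8
COL1A2	1066	sham	3.92	3.4
COL1A2	1066	7DPA	3.87	3.1
COL1A2	1066	14DPA	12.95	15.7
COL1A2	1066	30DPA	6.91	2.0
COL1A2	361	sham	0.96	0.3
COL1A2	361	7DPA	1.52	1.6
COL1A2	361	14DPA	4.66	4.5
COL1A2	361	30DPA	1.18	0.4
COL1A1b	404	sham	7.88	1.9
COL1A1b	404	7DPA	18.28	12.8
COL1A1b	404	14DPA	30.08	6.7
COL1A1b	404	30DPA	11.95	7.1
COL1A1b	554	sham	47.73	4.0
COL1A1b	554	7DPA	46.52	14.8
COL1A1b	554	14DPA	76.14	29.7
COL1A1b	554	30DPA	42.91	1.3
COL1A1b	914	sham	17.09	1.4
COL1A1b	914	7DPA	16.74	10.6
COL1A1b	914	14DPA	21.16	14.0
COL1A1b	914	30DPA	47.35	6.2
COL1A1b	1031	sham	12.44	16.1
COL1A1b	1031	7DPA	32.42	34.0
COL1A1b	1031	14DPA	18.31	24.2
COL1A1b	1031	30DPA	33.45	3.6
COL1A1b	1109	sham	10.36	7.6
COL1A1b	1109	7DPA	3.93	1.7
COL1A1b	1109	14DPA	4.76	6.0
COL1A1b	1109	30DPA	32.64	18.6
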