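lg	n_marker	n_snp	total_cM	avg_interval_cM	max_gap_cM	pct_gaps_lt5
LG2373	835	34278	116.59	0.14	1.3	100
LG2711	446	14688	145.62	0.33	3.22	100
LG4236	480	17664	140.77	0.29	4.05	100
LG4343	545	16824	175.06	0.32	2.65	100
LG5881	559	19318	163.13	0.29	2.39	100
LG5891	479	15862	153.28	0.32	3.22	100
LG10972	293	10189	119.09	0.41	2.65	100
LG11446	345	10877	122.16	0.36	4.31	100
LG11447	470	15522	142.25	0.3	3.53	100
LG11448	301	7296	150	0.5	4.36	100
LG11449	981	21940	183.49	0.19	2.13	100
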