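study	snp	rsid	genotype	row_type	controls_n	controls_pct	cases_n	cases_pct	controls_total	cases_total
NH	HSD3B2_23	rs1417608	GG	single	606	70.2	377	67.0	863	563
NH	HSD3B2_23	rs1417608	GA	single	182	21.1	100	17.8	863	563
NH	HSD3B2_23	rs1417608	AA	single	75	8.7	86	15.3	863	563
NH	HSD3B2_23	rs1417608	GA/AA	collapsed	257	29.8	186	33.1	863	563
TX	HSD3B2_proxy	rs1341015	TT	single	792	82.8	422	84.9	957	497
TX	HSD3B2_proxy	rs1341015	TC	single	161	16.8	68	13.7	957	497
TX	HSD3B2_proxy	rs1341015	CC	single	4	0.42	7	1.4	957	497
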