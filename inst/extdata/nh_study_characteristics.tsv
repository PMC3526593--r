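variable	level	column	n	printed_pct	column_total
gender	female	overall_controls	457	39.2	1167
gender	male	overall_controls	710	60.8	1167
gender	female	overall_cases	188	24.0	783
gender	male	overall_cases	595	76.0	783
gender	female	genotyped_controls	327	37.9	863
gender	male	genotyped_controls	536	62.1	863
gender	female	genotyped_cases	135	24.0	563
gender	male	genotyped_cases	428	76.0	563
reference_age	<40	overall_controls	55	4.7	1167
reference_age	40-49	overall_controls	143	12.3	1167
reference_age	50-59	overall_controls	226	19.4	1167
reference_age	60-69	overall_controls	467	40.0	1167
reference_age	>=70	overall_controls	276	23.7	1167
reference_age	<40	overall_cases	22	2.8	783
reference_age	40-49	overall_cases	58	7.4	783
reference_age	50-59	overall_cases	190	24.3	783
reference_age	60-69	overall_cases	324	41.4	783
reference_age	>=70	overall_cases	189	24.1	783
reference_age	<40	genotyped_controls	41	4.8	863
reference_age	40-49	genotyped_controls	86	10.0	863
reference_age	50-59	genotyped_controls	168	19.5	863
reference_age	60-69	genotyped_controls	356	41.3	863
reference_age	>=70	genotyped_controls	212	24.6	863
reference_age	<40	genotyped_cases	17	3.0	563
reference_age	40-49	genotyped_cases	37	6.6	563
reference_age	50-59	genotyped_cases	130	23.1	563
reference_age	60-69	genotyped_cases	242	43.0	563
reference_age	>=70	genotyped_cases	137	24.3	563
smoking	never	overall_controls	392	33.6	1167
smoking	former	overall_controls	566	48.5	1167
smoking	current	overall_controls	201	17.2	1167
smoking	never	overall_cases	131	16.7	783
smoking	former	overall_cases	385	49.2	783
smoking	current	overall_cases	254	32.4	783
smoking	never	genotyped_controls	292	33.8	863
smoking	former	genotyped_controls	432	50.1	863
smoking	current	genotyped_controls	139	16.1	863
smoking	never	genotyped_cases	98	17.4	563
smoking	former	genotyped_cases	273	48.5	563
smoking	current	genotyped_cases	191	33.9	563
stage	non-invasive	overall_cases	659	84.2	783
stage	invasive	overall_cases	79	10.1	783
stage	tis	overall_cases	45	5.7	783
stage	non-invasive	genotyped_cases	476	84.5	563
stage	invasive	genotyped_cases	55	9.8	563
stage	tis	genotyped_cases	32	5.7	563
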