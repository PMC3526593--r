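analysis	group	snp_a	genotype_a	snp_b	genotype_b	row_type	controls_n	cases_n	printed_or	printed_p_interaction
mdr	immune	GATA3_23	TT	CD81_04	GG	referent	689	488	1.0	NA
mdr	immune	GATA3_23	CT/CC	CD81_04	GA/AA	exposed	149	85	0.41	0.0003
sen	dna_repair	PMS1_26	TT/CT	NBS1_01b	CG/GG	referent	826	530	1.0	NA
sen	dna_repair	PMS1_26	CC	NBS1_01b	CC	exposed	36	35	4.15	0.0009
sen	immune	IRF3_01	AA/GG	IL6_01	CC/GG	referent	698	492	1.0	NA
sen	immune	IRF3_01	AG	IL6_01	CG	exposed	165	71	0.39	0.0001
sen	metabolism	COMT_28b	AA/GG	APOB_07	CT/TT	referent	619	436	1.0	NA
sen	metabolism	COMT_28b	AG	APOB_07	CC	exposed	234	122	0.35	0.0001
sen	metabolism	PTGS2_05	AA/GG	ABCC4_04	CC/TT	referent	788	516	1.0	NA
sen	metabolism	PTGS2_05	AG	ABCC4_04	CT	exposed	68	44	0.23	0.0001
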