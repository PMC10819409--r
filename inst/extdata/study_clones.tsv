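# CRISPR/Cas-engineered iPSC clones: edited locus, engineering method and per-clone WGS summary (hg19 coordinates)
clone_id	gene	clone_class	target_contig	target_start	target_end	cas_label	delivery	coverage	n_unique_snv	n_unique_indel	n_unique_sv
HNDS0068-01 #B CNC14	KCNQ2	CNC	chr20	62071008	62071027	Cas9	RNP	42.5	202	40	0
HNDS0068-01 #B CC3	KCNQ2	CC	chr20	62071008	62071027	Cas9	RNP	37.1	229	24	0
HNDS0078-01 #D CNC2	KCNQ2	CNC	chr20	62073830	62073848	Cas9	RNP	49.2	217	49	0
HNDS0078-01 #D CC8	KCNQ2	CC	chr20	62073830	62073848	Cas9	RNP	49.6	242	40	0
HNDS0078-01 #D CC18	KCNQ2	CC	chr20	62073830	62073848	Cas9	RNP	39.9	194	34	0
HNDS0072-01 #C CNC87	KCNQ2	CNC	chr20	62071037	62071056	Cas9	RNP	36.3	363	36	0
HNDS0072-01 #C CC80	KCNQ2	CC	chr20	62071037	62071056	Cas9	RNP	43.8	327	44	1
HNDS0072-01 #C CC20	KCNQ2	CC	chr20	62071037	62071056	Cas9	RNP	41.8	343	46	0
31 CC-het	GNAQ	CC	chr9	80412499	80412518	Cas9	plasmid	42.8	432	77	0
31 CC-hom	GNAQ	CC	chr9	80412499	80412518	Cas9	plasmid	33.4	792	73	1
1-1134-003_CNC5	ASH1L	CNC	chr1	155451881	155451901	Cas12a	RNP	45.4	190	48	0
1-1134-003_CC10	ASH1L	CC	chr1	155451881	155451901	Cas12a	RNP	45.2	220	46	0
1-1217-003_CNC36	ASH1L	CNC	chr1	155447747	155447768	Cas9	RNP	32.2	265	60	0
1-1217-003_CC37	ASH1L	CC	chr1	155447747	155447768	Cas9	RNP	39.2	260	64	0
1-1006-003_CNC35	ASH1L	CNC	chr1	155450703	155450723	Cas12a	RNP	39.4	268	64	0
1-1006-003_CC9	ASH1L	CC	chr1	155450703	155450723	Cas12a	RNP	44.3	234	71	0
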