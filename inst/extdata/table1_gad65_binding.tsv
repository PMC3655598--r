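peptide_id	sequence	cluster_score	ic50_drb1_0101	ic50_drb1_0401	ic50_drb1_0701	ic50_drb1_1501	published	dr4_predicted_inferred
GAD65_086-103	DVNYAFLHATDLLPACDG	12.19	<5	7.5	<5	NB	Y (NOT DR4)	TRUE
GAD65_175-190	HPRYFNQLSTGLDMVG	9.98	10.7	>50	13.9	NB	N	TRUE
GAD65_203-226	NMFTYEIAPVFVLLEYVTLKKMRE	14.70	NT	<25	NT	NT	Y (NOT DR4)	TRUE
GAD65_243-267	GAISNMYAMMIARFKMFPEVKEKGM	15.87	<5	NB	8.7	<5	Y (NOT DR4)	TRUE
GAD65_264-287	EKGMAALPRLIAFTSEHSHFSLKK	13.77	NT	<25	NT	NT	Y	TRUE
GAD65_338-352	TTVYGAFDPLLAVAD	9.69	4.1	NB	NB	31.3	Y (NOT DR4)	TRUE
GAD65_354-372	CKKYKIWMHVDAAWGGGLL	14.48	NB	6.4	<5	>50	Y	TRUE
GAD65_369-392	GGLLMSRKHKWKLSGVERANSVTW	17.60	16.3	<5	<5	NB	Y	TRUE
GAD65_405-424	SALLVREEGLMQNCNQMHAS	4.45	NB	>50	NB	NB	Y (NOT DR4)	TRUE
GAD65_450-470	VDVFKLWLMWRAKGTTGFEAH	33.90	25.4	NB	10.2	11.4	N	TRUE
GAD65_480-496	YLYNIIKNREGYEMVFD	5.90	<5	5.7	NB	<5	Y	TRUE
GAD65_504-518	VCFWYIPPSLRTLED	7.58	95.8	NB	25.2	10.3	Y	FALSE
GAD65_511-525	PSLRTLEDNEERMSR	-0.89	NB	NB	NB	NB	Y	FALSE
GAD65_550-570	LGDKVNFFRMVISNPAATHQD	22.32	NT	<25	NT	NT	Y	TRUE
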