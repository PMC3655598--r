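subject_id	cohort	stimulus	stimulus_type	sfc_without	sfc_with	significant
D1100H	diabetic	GAD65_450-470	peptide	-48	-48	FALSE
D1100H	diabetic	GAD65_550-570	peptide	199	141	FALSE
D1100H	diabetic	GAD65_504-518	peptide	101	-66	TRUE
D1100H	diabetic	GAD65_480-496	peptide	51	39	FALSE
D1100H	diabetic	GAD65_511-525	peptide	186	-44	TRUE
D1100H	diabetic	GAD65_264-287	peptide	91	33	FALSE
D1100H	diabetic	GAD65_369-392	peptide	1121	1351	FALSE
D1100H	diabetic	GAD65_355-372	peptide	205	515	FALSE
D1100H	diabetic	GAD65_086-103	peptide	149	106	FALSE
D1100H	diabetic	GAD65_protein	protein	413	77	FALSE
D1100H	diabetic	GAD65_pool	pool	1681	1429	FALSE
D1101H	diabetic	GAD65_450-470	peptide	260	324	FALSE
D1101H	diabetic	GAD65_550-570	peptide	126	100	FALSE
D1101H	diabetic	GAD65_504-518	peptide	31	-12	FALSE
D1101H	diabetic	GAD65_480-496	peptide	70	22	TRUE
D1101H	diabetic	GAD65_511-525	peptide	36	32	FALSE
D1101H	diabetic	GAD65_264-287	peptide	61	26	TRUE
D1101H	diabetic	GAD65_369-392	peptide	254	283	FALSE
D1101H	diabetic	GAD65_355-372	peptide	119	49	TRUE
D1101H	diabetic	GAD65_203-226	peptide	157	51	FALSE
D1101H	diabetic	GAD65_243-267	peptide	146	35	TRUE
D1101H	diabetic	GAD65_405-424	peptide	71	56	FALSE
D1101H	diabetic	GAD65_086-103	peptide	69	38	FALSE
D1101H	diabetic	GAD65_338-354	peptide	76	44	FALSE
D1101H	diabetic	GAD65_175-190	peptide	40	23	FALSE
D1101H	diabetic	GAD65_protein	protein	37	59	FALSE
D1101H	diabetic	GAD65_pool	pool	403	259	FALSE
D1104H	diabetic	GAD65_450-470	peptide	77	69	FALSE
D1104H	diabetic	GAD65_550-570	peptide	146	101	FALSE
D1104H	diabetic	GAD65_504-518	peptide	72	11	FALSE
D1104H	diabetic	GAD65_480-496	peptide	129	41	TRUE
D1104H	diabetic	GAD65_511-525	peptide	6	26	FALSE
D1104H	diabetic	GAD65_264-287	peptide	141	154	FALSE
D1104H	diabetic	GAD65_369-392	peptide	434	266	TRUE
D1104H	diabetic	GAD65_355-372	peptide	151	268	FALSE
D1104H	diabetic	GAD65_203-226	peptide	221	154	FALSE
D1104H	diabetic	GAD65_243-267	peptide	71	54	FALSE
D1104H	diabetic	GAD65_405-424	peptide	126	64	FALSE
D1104H	diabetic	GAD65_086-103	peptide	21	1	FALSE
D1104H	diabetic	GAD65_338-354	peptide	54	-4	TRUE
D1104H	diabetic	GAD65_175-190	peptide	72	59	FALSE
D1104H	diabetic	GAD65_protein	protein	32	69	FALSE
D1104H	diabetic	GAD65_pool	pool	391	378	FALSE
D1105H	diabetic	GAD65_450-470	peptide	73	19	TRUE
D1105H	diabetic	GAD65_550-570	peptide	352	228	TRUE
D1105H	diabetic	GAD65_504-518	peptide	77	28	FALSE
D1105H	diabetic	GAD65_480-496	peptide	75	4	FALSE
D1105H	diabetic	GAD65_511-525	peptide	2	-4	FALSE
D1105H	diabetic	GAD65_264-287	peptide	205	138	TRUE
D1105H	diabetic	GAD65_369-392	peptide	468	406	FALSE
D1105H	diabetic	GAD65_355-372	peptide	488	509	FALSE
D1105H	diabetic	GAD65_203-226	peptide	245	138	TRUE
D1105H	diabetic	GAD65_243-267	peptide	30	274	FALSE
D1105H	diabetic	GAD65_086-103	peptide	-32	76	FALSE
D1105H	diabetic	GAD65_pool	pool	645	579	FALSE
D1106H	diabetic	GAD65_450-470	peptide	155	24	TRUE
D1106H	diabetic	GAD65_550-570	peptide	88	113	FALSE
D1106H	diabetic	GAD65_504-518	peptide	82	74	FALSE
D1106H	diabetic	GAD65_480-496	peptide	70	88	FALSE
D1106H	diabetic	GAD65_511-525	peptide	54	23	FALSE
D1106H	diabetic	GAD65_264-287	peptide	173	66	TRUE
D1106H	diabetic	GAD65_203-226	peptide	207	138	FALSE
D1106H	diabetic	GAD65_243-267	peptide	134	144	FALSE
D1106H	diabetic	GAD65_405-424	peptide	324	365	FALSE
D1106H	diabetic	GAD65_086-103	peptide	59	46	FALSE
D1106H	diabetic	GAD65_338-354	peptide	48	24	FALSE
D1106H	diabetic	GAD65_175-190	peptide	33	17	FALSE
D1106H	diabetic	GAD65_protein	protein	670	591	FALSE
D1106H	diabetic	GAD65_pool	pool	552	543	FALSE
D1107H	diabetic	GAD65_450-470	peptide	22	-18	TRUE
D1107H	diabetic	GAD65_550-570	peptide	160	1	TRUE
D1107H	diabetic	GAD65_504-518	peptide	7	-18	FALSE
D1107H	diabetic	GAD65_480-496	peptide	42	-3	FALSE
D1107H	diabetic	GAD65_511-525	peptide	18	-13	FALSE
D1107H	diabetic	GAD65_264-287	peptide	48	-4	TRUE
D1107H	diabetic	GAD65_086-103	peptide	13	-19	FALSE
D1107H	diabetic	GAD65_protein	protein	95	46	FALSE
D1107H	diabetic	GAD65_pool	pool	262	9	TRUE
N669C	control	GAD65_450-470	peptide	33	13	FALSE
N669C	control	GAD65_550-570	peptide	144	30	TRUE
N669C	control	GAD65_504-518	peptide	24	27	FALSE
N669C	control	GAD65_480-496	peptide	313	98	TRUE
N669C	control	GAD65_511-525	peptide	13	-17	TRUE
N669C	control	GAD65_264-287	peptide	26	12	FALSE
N669C	control	GAD65_203-226	peptide	109	52	FALSE
N669C	control	GAD65_243-267	peptide	21	-12	FALSE
N669C	control	GAD65_405-424	peptide	78	13	TRUE
N669C	control	GAD65_086-103	peptide	11	5	FALSE
N669C	control	GAD65_175-190	peptide	39	-3	FALSE
N669C	control	GAD65_pool	pool	76	30	FALSE
N668C	control	GAD65_450-470	peptide	125	-10	TRUE
N668C	control	GAD65_550-570	peptide	312	440	FALSE
N668C	control	GAD65_504-518	peptide	222	75	TRUE
N668C	control	GAD65_480-496	peptide	195	193	FALSE
N668C	control	GAD65_511-525	peptide	138	103	FALSE
N668C	control	GAD65_264-287	peptide	813	593	FALSE
N668C	control	GAD65_203-226	peptide	475	460	FALSE
N668C	control	GAD65_243-267	peptide	287	207	TRUE
N668C	control	GAD65_405-424	peptide	178	-8	TRUE
N668C	control	GAD65_086-103	peptide	143	128	FALSE
N668C	control	GAD65_pool	pool	820	692	FALSE
N674C	control	GAD65_450-470	peptide	396	464	FALSE
N674C	control	GAD65_550-570	peptide	490	431	FALSE
N674C	control	GAD65_504-518	peptide	21	76	FALSE
N674C	control	GAD65_480-496	peptide	162	69	TRUE
N674C	control	GAD65_511-525	peptide	19	24	FALSE
N674C	control	GAD65_264-287	peptide	183	153	FALSE
N674C	control	GAD65_369-392	peptide	750	531	TRUE
N674C	control	GAD65_355-372	peptide	72	17	TRUE
N674C	control	GAD65_203-226	peptide	168	109	FALSE
N674C	control	GAD65_243-267	peptide	161	134	FALSE
N674C	control	GAD65_405-424	peptide	16	26	FALSE
N674C	control	GAD65_086-103	peptide	51	34	FALSE
N674C	control	GAD65_338-354	peptide	4	14	FALSE
N674C	control	GAD65_175-190	peptide	11	8	FALSE
N674C	control	GAD65_protein	protein	44	818	FALSE
N674C	control	GAD65_pool	pool	613	42	FALSE
N670C	control	GAD65_450-470	peptide	115	23	TRUE
N670C	control	GAD65_550-570	peptide	25	-90	FALSE
N670C	control	GAD65_504-518	peptide	39	-26	FALSE
N670C	control	GAD65_480-496	peptide	-28	-81	FALSE
N670C	control	GAD65_511-525	peptide	36	-79	FALSE
N670C	control	GAD65_264-287	peptide	129	19	FALSE
N670C	control	GAD65_203-226	peptide	329	82	TRUE
N670C	control	GAD65_243-267	peptide	188	-9	TRUE
N670C	control	GAD65_405-424	peptide	49	-14	FALSE
N670C	control	GAD65_086-103	peptide	27	-9	FALSE
N670C	control	GAD65_175-190	peptide	53	-7	TRUE
N670C	control	GAD65_pool	pool	117	-19	FALSE
N672C	control	GAD65_450-470	peptide	-98	63	FALSE
N672C	control	GAD65_504-518	peptide	0	133	FALSE
N672C	control	GAD65_480-496	peptide	8	49	FALSE
N672C	control	GAD65_511-525	peptide	52	113	FALSE
N672C	control	GAD65_264-287	peptide	5	39	FALSE
N672C	control	GAD65_243-267	peptide	67	59	FALSE
N672C	control	GAD65_405-424	peptide	-10	11	FALSE
N672C	control	GAD65_086-103	peptide	-27	16	FALSE
N672C	control	GAD65_pool	pool	100	48	FALSE
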