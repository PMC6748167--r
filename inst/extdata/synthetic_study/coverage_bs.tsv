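probe_id	S001	S002	S003	S004	S005	S006	S007	S008	S009	S010
probe_00001	116	104	93	79	131	154	69	102	102	87
probe_00002	97	62	109	81	88	76	70	112	87	89
probe_00003	104	106	109	123	138	94	95	75	105	89
probe_00004	71	101	95	88	80	103	100	84	136	56
probe_00005	112	156	76	74	146	170	84	72	51	103
probe_00006	110	120	134	50	162	91	134	82	93	130
probe_00007	72	90	75	118	130	72	79	63	89	111
probe_00008	131	114	84	87	93	103	136	86	102	39
probe_00009	114	100	134	78	144	101	112	78	86	60
probe_00010	90	97	69	98	99	85	92	96	101	136
probe_00011	67	146	141	99	120	104	89	102	113	68
probe_00012	88	66	102	116	118	128	165	108	103	123
probe_00013	105	106	93	87	93	121	84	65	108	101
probe_00014	129	110	83	148	67	140	96	126	105	59
probe_00015	115	89	103	97	80	95	109	87	103	107
probe_00016	103	69	84	130	98	91	88	103	94	99
probe_00017	107	77	120	71	112	131	142	108	126	116
probe_00018	112	85	97	76	127	86	117	67	63	147
probe_00019	107	66	128	120	119	105	81	135	128	124
probe_00020	121	79	155	94	100	92	77	95	133	77
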