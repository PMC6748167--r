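probe_id	S001	S002	S003	S004	S005	S006	S007	S008	S009	S010
probe_00001	111	107	87	91	101	116	73	143	84	153
probe_00002	116	135	107	88	111	127	40	89	85	113
probe_00003	104	106	109	123	138	94	95	75	105	89
probe_00004	118	99	85	72	112	132	86	71	123	107
probe_00005	138	98	100	78	132	138	79	120	87	61
probe_00006	85	83	58	96	113	124	126	63	64	80
probe_00007	65	98	146	92	63	138	149	106	79	120
probe_00008	88	80	126	95	89	139	138	120	115	87
probe_00009	141	152	42	75	94	116	112	103	96	129
probe_00010	97	135	104	79	58	65	86	84	62	121
probe_00011	50	121	98	82	116	117	126	71	126	67
probe_00012	88	155	77	113	65	114	97	55	108	65
probe_00013	103	68	101	78	94	73	74	114	96	84
probe_00014	79	152	104	134	151	124	73	94	109	101
probe_00015	117	70	145	61	108	52	123	87	141	128
probe_00016	105	119	111	134	93	63	71	68	114	73
probe_00017	127	107	137	69	94	71	82	101	84	113
probe_00018	89	77	104	136	134	104	95	100	95	136
probe_00019	115	125	57	114	89	75	96	82	102	117
probe_00020	74	105	78	92	69	161	90	117	88	90
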