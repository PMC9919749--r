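# predsip synthetic fixture (simulated SIP gradients)
# simulator seed: 20240801
taxon	C13_E_coli_24h:1	C13_E_coli_24h:2	C13_E_coli_24h:3	C13_E_coli_24h:4	C13_E_coli_24h:5	C13_E_coli_24h:6	C13_E_coli_24h:7	C13_E_coli_24h:8	C13_E_coli_24h:9	C13_E_coli_24h:10	C13_E_coli_24h:11	C13_E_coli_24h:12	C13_E_coli_24h:13	C12_E_coli_24h:1	C12_E_coli_24h:2	C12_E_coli_24h:3	C12_E_coli_24h:4	C12_E_coli_24h:5	C12_E_coli_24h:6	C12_E_coli_24h:7	C12_E_coli_24h:8	C12_E_coli_24h:9	C12_E_coli_24h:10	C12_E_coli_24h:11	C12_E_coli_24h:12	C12_E_coli_24h:13
ASV001	525	522	536	559	508	518	36	0	0	0	0	0	0	449	469	417	459	488	453	427	473	438	426	437	433	449
ASV002	279	276	262	235	253	219	16	0	0	0	0	0	0	210	177	210	211	204	215	203	190	207	208	223	199	212
ASV003	166	197	220	191	198	218	1264	1357	1361	1389	1392	1349	1366	413	410	414	420	395	388	399	385	409	420	425	413	365
ASV004	190	154	195	170	160	196	16	0	0	0	0	0	0	115	108	143	133	150	142	141	105	154	141	131	144	148
ASV005	163	162	141	135	150	143	13	0	0	0	0	0	0	129	110	123	119	118	118	106	121	111	116	113	132	126
ASV006	109	122	121	146	142	115	15	0	0	0	0	0	0	89	121	113	84	98	112	100	111	108	108	103	108	112
ASV007	46	30	25	39	49	50	298	314	311	317	282	310	331	92	104	92	96	76	88	95	78	79	96	85	69	87
ASV008	261	266	260	271	281	273	24	0	0	0	0	0	0	199	220	231	240	217	224	248	252	239	215	220	206	237
ASV009	85	99	66	98	88	80	9	0	0	0	0	0	0	86	83	68	74	78	71	64	81	72	79	60	74	71
ASV010	157	141	157	143	145	144	14	0	0	0	0	0	0	137	107	107	96	103	98	125	134	120	107	122	134	101
ASV011	8	12	7	2	13	27	243	279	268	241	278	271	252	58	65	62	56	51	69	70	57	52	55	59	51	58
ASV012	11	19	10	11	13	16	4	0	0	0	0	0	0	10	15	14	9	11	14	14	8	8	12	14	20	20
ASV_prey_Ec	0	0	0	0	0	1	48	50	60	53	48	70	51	13	11	6	3	11	8	8	5	3	17	8	17	14
ASV_prey_Pp	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
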