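snp	chrom	bp	casesHom	casesHet	controlsHom	controlsHet	chi2Printed	pPrinted	qPrinted
rs4698482	4	16020011	519	116	274	157	44.43	2.62e-11	1.40e-5
rs1168884	2	204624451	512	119	275	156	40.10	2.40e-10	5.38e-5
rs9578483	13	22068754	543	97	296	135	39.66	3.01e-10	5.38e-5
rs839509	2	212530542	497	126	270	160	37.09	1.12e-9	0.0001
rs2414003	15	48105489	514	122	280	151	33.90	5.77e-9	0.0006
rs3096381	16	69875502	525	116	289	141	30.46	3.39e-8	0.0028
rs630695	6	117359452	526	103	299	132	30.10	4.09e-8	0.0028
rs938845	18	63860975	512	122	284	147	30.02	4.26e-8	0.0028
rs17797954	5	174303096	516	122	287	144	28.09	1.15e-7	0.0068
rs10961997	9	15361675	509	134	279	152	27.48	1.58e-7	0.0083
rs12126497	1	166939482	586	56	346	85	27.33	1.71e-7	0.0083
rs509716	6	131475408	532	113	297	134	26.90	2.13e-7	0.0095
rs6715968	2	229884476	484	141	272	159	25.75	3.86e-7	0.0159
rs712082	1	222792683	545	98	311	120	25.32	4.83e-7	0.0173
rs6440553	3	149713261	545	84	321	110	25.32	4.84e-7	0.0173
rs8043171	15	90065471	529	105	304	127	25.07	5.50e-7	0.0184
rs12902263	15	69429108	556	87	321	110	24.77	6.44e-7	0.0197
rs10254361	7	119351441	522	116	296	135	24.72	6.62e-7	0.0197
rs11563992	7	27347461	507	115	294	136	24.16	8.86e-7	0.0242
rs7018634	9	20249528	538	100	310	121	24.11	9.05e-7	0.0242
rs11169076	12	48261675	571	72	335	96	23.99	9.68e-7	0.0247
rs1943939	18	69856260	556	62	342	89	23.22	1.43e-6	0.0332
rs12660310	6	167051901	503	120	292	139	23.18	1.46e-6	0.0332
rs11204947	1	150484881	489	135	280	151	23.16	1.48e-6	0.0332
rs3821310	2	74923771	581	61	345	85	23.06	1.56e-6	0.0335
rs9407406	9	8229748	532	95	314	117	22.93	1.67e-6	0.0345
rs2830028	21	26349119	493	133	282	148	22.64	1.94e-6	0.0386
rs11151652	18	67133203	554	91	319	110	22.52	2.07e-6	0.0397
rs10779770	1	12529312	537	97	314	117	22.42	2.18e-6	0.0403
rs1508833	5	38050010	519	108	303	127	22.35	2.26e-6	0.0404
rs5542328	10	25337605	540	98	314	117	22.23	2.40e-6	0.0408
rs2102727	8	53063166	502	133	285	146	22.21	2.43e-6	0.0408
rs9379246	6	8777273	571	67	341	90	22.11	2.56e-6	0.0416
rs7481683	11	8157762	454	174	252	179	21.98	2.75e-6	0.0434
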