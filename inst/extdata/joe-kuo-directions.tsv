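# Joe-Kuo direction numbers (new-joe-kuo-6), first 128 dimensions
# columns: dim poly m1..ms  (poly encodes the primitive polynomial bits; s = floor(log2(poly)))
1	1	1
2	3	1
3	7	1	3
4	11	1	3	1
5	13	1	1	1
6	19	1	1	3	3
7	25	1	3	5	13
8	37	1	1	5	5	17
9	41	1	1	5	5	5
10	47	1	1	7	11	19
11	55	1	1	5	1	1
12	59	1	1	1	3	11
13	61	1	3	5	5	31
14	67	1	3	3	9	7	49
15	91	1	1	1	15	21	21
16	97	1	3	1	13	27	49
17	103	1	1	1	15	7	5
18	109	1	3	1	15	13	25
19	115	1	1	5	5	19	61
20	131	1	3	7	11	23	15	103
21	137	1	3	7	13	13	15	69
22	143	1	1	3	13	7	35	63
23	145	1	3	5	9	1	25	53
24	157	1	3	1	13	9	35	107
25	167	1	3	1	5	27	61	31
26	171	1	1	5	11	19	41	61
27	185	1	3	5	3	3	13	69
28	191	1	1	7	13	1	19	1
29	193	1	3	7	5	13	19	59
30	203	1	1	3	9	25	29	41
31	211	1	3	5	13	23	1	55
32	213	1	3	7	3	13	59	17
33	229	1	3	1	3	5	53	69
34	239	1	1	5	5	23	33	13
35	241	1	1	7	7	1	61	123
36	247	1	1	7	9	13	61	49
37	253	1	3	3	5	3	55	33
38	285	1	3	1	15	31	13	49	245
39	299	1	3	5	15	31	59	63	97
40	301	1	3	1	11	11	11	77	249
41	333	1	3	1	11	27	43	71	9
42	351	1	1	7	15	21	11	81	45
43	355	1	3	7	3	25	31	65	79
44	357	1	3	1	1	19	11	3	205
45	361	1	1	5	9	19	21	29	157
46	369	1	3	7	11	1	33	89	185
47	391	1	3	3	3	15	9	79	71
48	397	1	3	7	11	15	39	119	27
49	425	1	1	3	1	11	31	97	225
50	451	1	1	1	3	23	43	57	177
51	463	1	3	7	7	17	17	37	71
52	487	1	3	1	5	27	63	123	213
53	501	1	1	3	5	11	43	53	133
54	529	1	3	5	5	29	17	47	173	479
55	539	1	3	3	11	3	1	109	9	69
56	545	1	1	1	5	17	39	23	5	343
57	557	1	3	1	5	25	15	31	103	499
58	563	1	1	1	11	11	17	63	105	183
59	601	1	1	5	11	9	29	97	231	363
60	607	1	1	5	15	19	45	41	7	383
61	617	1	3	7	7	31	19	83	137	221
62	623	1	1	1	3	23	15	111	223	83
63	631	1	1	5	13	31	15	55	25	161
64	637	1	1	3	13	25	47	39	87	257
65	647	1	1	1	11	21	53	125	249	293
66	661	1	1	7	11	11	7	57	79	323
67	675	1	1	5	5	17	13	81	3	131
68	677	1	1	7	13	23	7	65	251	475
69	687	1	3	5	1	9	43	3	149	11
70	695	1	1	3	13	31	13	13	255	487
71	701	1	3	3	1	5	63	89	91	127
72	719	1	1	3	3	1	19	123	127	237
73	721	1	1	5	7	23	31	37	243	289
74	731	1	1	5	11	17	53	117	183	491
75	757	1	1	1	5	1	13	13	209	345
76	761	1	1	3	15	1	57	115	7	33
77	787	1	3	1	11	7	43	81	207	175
78	789	1	3	1	1	15	27	63	255	49
79	799	1	3	5	3	27	61	105	171	305
80	803	1	1	5	3	1	3	57	249	149
81	817	1	1	3	5	5	57	15	13	159
82	827	1	1	1	11	7	11	105	141	225
83	847	1	3	3	5	27	59	121	101	271
84	859	1	3	5	9	11	49	51	59	115
85	865	1	1	7	1	23	45	125	71	419
86	875	1	1	3	5	23	5	105	109	75
87	877	1	1	7	15	7	11	67	121	453
88	883	1	3	7	3	9	13	31	27	449
89	895	1	3	1	15	19	39	39	89	15
90	901	1	1	1	1	1	33	73	145	379
91	911	1	3	1	15	15	43	29	13	483
92	949	1	1	7	3	19	27	85	131	431
93	953	1	3	3	3	5	35	23	195	349
94	967	1	3	3	7	9	27	39	59	297
95	971	1	1	3	9	11	17	13	241	157
96	973	1	3	7	15	25	57	33	189	213
97	981	1	1	7	1	9	55	73	83	217
98	985	1	3	3	13	19	27	23	113	249
99	995	1	3	5	3	23	43	3	253	479
100	1001	1	1	5	5	11	5	45	117	217
101	1019	1	3	3	7	29	37	33	123	147
102	1033	1	3	1	15	5	5	37	227	223	459
103	1051	1	1	7	5	5	39	63	255	135	487
104	1063	1	3	1	7	9	7	87	249	217	599
105	1069	1	1	3	13	9	47	7	225	363	247
106	1125	1	3	7	13	19	13	9	67	9	737
107	1135	1	3	5	5	19	59	7	41	319	677
108	1153	1	1	5	3	31	63	15	43	207	789
109	1163	1	1	7	9	13	39	3	47	497	169
110	1221	1	3	1	7	21	17	97	19	415	905
111	1239	1	3	7	1	3	31	71	111	165	127
112	1255	1	1	5	11	1	61	83	119	203	847
113	1267	1	3	3	13	9	61	19	97	47	35
114	1279	1	1	7	7	15	29	63	95	417	469
115	1293	1	3	1	9	25	9	71	57	213	385
116	1305	1	3	5	13	31	47	101	57	39	341
117	1315	1	1	3	3	31	57	125	173	365	551
118	1329	1	3	7	1	13	57	67	157	451	707
119	1341	1	1	1	7	21	13	105	89	429	965
120	1347	1	1	5	9	17	51	45	119	157	141
121	1367	1	3	7	7	13	45	91	9	129	741
122	1387	1	3	7	1	23	57	67	141	151	571
123	1413	1	1	3	11	17	47	93	107	375	157
124	1423	1	3	3	5	11	21	43	51	169	915
125	1431	1	1	5	3	15	55	101	67	455	625
126	1441	1	3	5	9	1	23	29	47	345	595
127	1479	1	3	7	7	5	49	29	155	323	589
128	1509	1	3	3	7	5	41	127	61	261	717
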