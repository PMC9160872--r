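transcript_id	F1_30C_r1	F1_30C_r2	F1_30C_r3	F1_16C_r1	F1_16C_r2	F1_16C_r3	F1_4C_r1	F1_4C_r2	F1_4C_r3
SPT_0001	571	562	704	639	663	1010	3052	3283	2970
SPT_0002	2796	4358	3442	6117	8332	6939	936	1128	1568
SPT_0003	40	57	74	490	453	480	102	132	107
SPT_0004	49	36	67	77	68	29	30	34	54
SPT_0005	329	252	246	504	509	567	408	272	619
SPT_0006	261	432	431	1630	1741	1568	489	626	322
SPT_0007	260	247	208	147	268	190	844	1032	742
SPT_0008	444	337	358	382	365	552	414	442	401
SPT_0009	947	592	676	1042	967	556	833	578	733
SPT_0010	193	192	130	567	874	553	183	220	124
SPT_0011	115	169	200	499	726	1045	170	131	170
SPT_0012	88	118	86	64	41	32	69	71	103
SPT_0013	614	712	1519	1043	879	1090	382	564	374
SPT_0014	693	637	539	597	433	660	344	281	247
SPT_0015	248	166	149	194	136	187	89	167	150
SPT_0016	118	220	170	247	300	147	79	82	115
SPT_0017	246	166	252	65	50	34	65	45	62
SPT_0018	2435	1088	1187	4370	3055	2821	1308	2051	1179
SPT_0019	756	533	505	514	625	507	609	373	508
SPT_0020	611	749	644	750	495	755	558	854	967
SPC_0001	256	204	288	246	491	213	996	674	1168
SPC_0002	5443	3812	4225	8070	8050	7227	1362	1530	2371
SPC_0003	334	330	473	3083	2215	2458	426	502	642
SPC_0004	143	257	252	232	198	179	227	226	147
SPC_0005	356	404	406	1024	1083	938	624	1188	700
SPC_0006	152	106	168	922	760	643	147	140	147
SPC_0007	189	230	316	308	300	187	1004	743	1096
SPC_0008	690	694	589	754	716	477	511	771	715
SPC_0009	292	331	247	258	320	426	251	211	246
SPC_0010	882	486	669	3105	2352	3222	435	587	547
SPC_0011	39	33	31	158	142	135	25	49	32
SPC_0012	196	245	214	125	134	75	234	313	243
SPC_0013	401	307	348	369	290	411	121	239	179
SPC_0014	398	381	473	587	604	409	264	108	125
SPC_0015	202	181	310	327	346	391	245	287	249
SPC_0016	332	456	346	361	328	356	194	158	165
SPC_0017	511	256	238	27	59	133	62	86	65
SPC_0018	360	271	519	1299	1068	991	295	546	439
SPC_0019	1260	1192	1130	855	1291	1104	904	1005	1291
SPC_0020	445	347	431	589	398	242	296	210	270
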