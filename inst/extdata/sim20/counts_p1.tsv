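transcript_id	P1_30C_r1	P1_30C_r2	P1_30C_r3	P1_16C_r1	P1_16C_r2	P1_16C_r3	P1_4C_r1	P1_4C_r2	P1_4C_r3
SPT_0001	1412	1257	971	2179	1895	1851	1196	1574	1091
SPT_0002	2331	2775	3803	12573	10451	12274	3483	2453	2759
SPT_0003	1135	867	763	877	1143	1006	839	1028	1223
SPT_0004	464	451	681	581	401	534	2661	1811	2172
SPT_0005	3368	3801	3307	1000	913	1177	1014	726	904
SPT_0006	1370	980	1135	907	1076	438	914	507	880
SPT_0007	445	592	341	418	324	494	531	376	452
SPT_0008	946	1040	448	854	1418	1030	701	800	1117
SPT_0009	2041	2025	1647	2445	1829	2171	5877	9547	5057
SPT_0010	428	372	289	248	334	500	361	266	358
SPT_0011	189	146	166	160	139	154	184	152	159
SPT_0012	219	217	184	628	572	775	174	154	165
SPT_0013	1499	3033	1697	1448	1894	1636	1751	1689	2124
SPT_0014	1349	1501	1418	1440	1072	1029	4253	5622	4755
SPT_0015	484	291	397	260	266	335	408	318	353
SPT_0016	541	575	241	1347	1820	1052	317	478	355
SPT_0017	536	484	415	104	90	137	104	114	115
SPT_0018	1494	1363	2090	2050	1791	2015	2086	995	1591
SPT_0019	1090	1055	940	1226	1245	786	940	965	806
SPT_0020	905	1210	1115	1029	1273	1492	1081	1594	1378
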