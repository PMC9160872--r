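transcript_id	P2_30C_r1	P2_30C_r2	P2_30C_r3	P2_16C_r1	P2_16C_r2	P2_16C_r3	P2_4C_r1	P2_4C_r2	P2_4C_r3
SPC_0001	588	446	707	280	538	463	2961	1919	2675
SPC_0002	19380	12910	12692	2990	3738	4530	3528	2679	3042
SPC_0003	1641	3242	3787	2875	2398	2789	756	559	598
SPC_0004	287	150	188	299	208	293	198	229	251
SPC_0005	1580	1045	1612	926	1815	1480	1746	1540	1508
SPC_0006	227	184	357	1173	1423	1498	237	443	297
SPC_0007	435	519	574	570	624	420	1779	2282	1658
SPC_0008	1123	570	1353	1475	1190	1058	1502	1392	1214
SPC_0009	580	455	592	495	718	566	701	709	413
SPC_0010	1029	1222	1325	3975	4453	4533	1164	1376	1070
SPC_0011	242	153	329	946	1106	1340	294	311	173
SPC_0012	488	534	412	810	373	445	491	729	574
SPC_0013	990	561	646	816	704	501	902	1093	1056
SPC_0014	511	490	707	2174	2577	2716	892	1058	948
SPC_0015	618	630	635	466	622	697	425	744	510
SPC_0016	662	785	603	528	725	561	908	835	506
SPC_0017	186	148	180	158	163	182	186	182	94
SPC_0018	1807	2432	2936	8169	7948	14536	2538	3251	1683
SPC_0019	1316	1359	2627	2058	2490	1579	2415	1866	1281
SPC_0020	564	340	589	510	763	506	401	544	780
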