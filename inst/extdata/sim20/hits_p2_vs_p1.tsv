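SPC_0001	SPT_0001	97.5	1120	28	0	1	1120	1	1120	0	2016
SPC_0002	SPT_0002	97.5	1676	42	0	1	1676	1	1676	0	3017
SPC_0003	SPT_0003	97.5	1359	34	0	1	1359	1	1359	0	2446
SPC_0004	SPT_0004	97.5	758	19	0	1	758	1	758	0	1364
SPC_0005	SPT_0005	97.5	1133	28	0	1	1133	1	1133	0	2039
SPC_0006	SPT_0006	97.5	980	24	0	1	980	1	980	0	1764
SPC_0007	SPT_0007	97.5	1651	41	0	1	1651	1	1651	0	2972
SPC_0008	SPT_0008	97.5	1826	46	0	1	1826	1	1826	0	3287
SPC_0009	SPT_0009	97.5	798	20	0	1	798	1	798	0	1436
SPC_0010	SPT_0010	97.5	855	21	0	1	855	1	855	0	1539
SPC_0011	SPT_0011	97.5	2124	53	0	1	2124	1	2124	0	3823
SPC_0012	SPT_0012	97.5	664	17	0	1	664	1	664	0	1195
SPC_0013	SPT_0013	97.5	1335	33	0	1	1335	1	1335	0	2403
SPC_0014	SPT_0014	97.5	1481	37	0	1	1481	1	1481	0	2666
SPC_0015	SPT_0015	97.5	1398	35	0	1	1398	1	1398	0	2516
SPC_0016	SPT_0016	97.5	1100	28	0	1	1100	1	1100	0	1980
SPC_0017	SPT_0017	97.5	1806	45	0	1	1806	1	1806	0	3251
SPC_0018	SPT_0018	97.5	1431	36	0	1	1431	1	1431	0	2576
SPC_0019	SPT_0019	97.5	1496	37	0	1	1496	1	1496	0	2693
SPC_0020	SPT_0020	97.5	1226	31	0	1	1226	1	1226	0	2207
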