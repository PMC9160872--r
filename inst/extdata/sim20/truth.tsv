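pair_id	p1_id	p2_id	condition	bin	true_b	expr_p1	expr_p2	expr_hybrid	len_spt	len_spc
SPT_0001|SPC_0001	SPT_0001	SPC_0001	30C	no_change	0	1.02191819351257	1.02191819351257	1.02191819351257	2868	1120
SPT_0002|SPC_0002	SPT_0002	SPC_0002	30C	additivity	0	3.55890661809795	14.2356264723918	8.89726654524487	1676	2040
SPT_0003|SPC_0003	SPT_0003	SPC_0003	30C	transgressive_down	-2.81604883953668	1.10568443632845	4.4227377453138	0.552842218164225	1597	1359
SPT_0004|SPC_0004	SPT_0004	SPC_0004	30C	no_change	-2.92388867070197	0.589841208100955	0.589841208100955	0.589841208100955	1751	758
SPT_0005|SPC_0005	SPT_0005	SPC_0005	30C	transgressive_down	0	7.05998033496708	1.76499508374177	0.882497541870886	1133	1837
SPT_0006|SPC_0006	SPT_0006	SPC_0006	30C	no_change	0	0.655254991192976	0.655254991192976	0.655254991192976	2596	980
SPT_0007|SPC_0007	SPT_0007	SPC_0007	30C	no_change	0	0.523665780610215	0.523665780610215	0.523665780610215	1651	1821
SPT_0008|SPC_0008	SPT_0008	SPC_0008	30C	no_change	0	0.969477640500901	0.969477640500901	0.969477640500901	1826	2571
SPT_0009|SPC_0009	SPT_0009	SPC_0009	30C	no_change	0	1.41702185170964	1.41702185170964	1.41702185170964	2571	798
SPT_0010|SPC_0010	SPT_0010	SPC_0010	30C	no_change	0	0.826621379787273	0.826621379787273	0.826621379787273	855	2953
SPT_0011|SPC_0011	SPT_0011	SPC_0011	30C	no_change	2.57452636103147	0.169967526531709	0.169967526531709	0.169967526531709	2124	2861
SPT_0012|SPC_0012	SPT_0012	SPC_0012	30C	no_change	0	0.547790298307074	0.547790298307074	0.547790298307074	664	1815
SPT_0013|SPC_0013	SPT_0013	SPC_0013	30C	no_change	0	1.25123659010107	1.25123659010107	1.25123659010107	2957	1335
SPT_0014|SPC_0014	SPT_0014	SPC_0014	30C	no_change	0	1.10090559372946	1.10090559372946	1.10090559372946	2402	1481
SPT_0015|SPC_0015	SPT_0015	SPC_0015	30C	no_change	0	0.447300332749273	0.447300332749273	0.447300332749273	1398	2693
SPT_0016|SPC_0016	SPT_0016	SPC_0016	30C	no_change	0	0.736629610753631	0.736629610753631	0.736629610753631	1100	1871
SPT_0017|SPC_0017	SPT_0017	SPC_0017	30C	ELD_P1	0	0.4919149308472	0.1229787327118	0.4919149308472	1806	2744
SPT_0018|SPC_0018	SPT_0018	SPC_0018	30C	no_change	2.16049980894538	2.45779750167539	2.45779750167539	2.45779750167539	1431	2039
SPT_0019|SPC_0019	SPT_0019	SPC_0019	30C	no_change	0	1.45520381756398	1.45520381756398	1.45520381756398	1496	2773
SPT_0020|SPC_0020	SPT_0020	SPC_0020	30C	no_change	0	1.02291897964805	1.02291897964805	1.02291897964805	2514	1226
SPT_0001|SPC_0001	SPT_0001	SPC_0001	16C	no_change	0	1.02191819351257	1.02191819351257	1.02191819351257	2868	1120
SPT_0002|SPC_0002	SPT_0002	SPC_0002	16C	ELD_P1	0	14.2356264723918	3.55890661809795	14.2356264723918	1676	2040
SPT_0003|SPC_0003	SPT_0003	SPC_0003	16C	ELD_P2	-2.81604883953668	1.10568443632845	4.4227377453138	4.4227377453138	1597	1359
SPT_0004|SPC_0004	SPT_0004	SPC_0004	16C	no_change	-2.92388867070197	0.589841208100955	0.589841208100955	0.589841208100955	1751	758
SPT_0005|SPC_0005	SPT_0005	SPC_0005	16C	no_change	0	1.76499508374177	1.76499508374177	1.76499508374177	1133	1837
SPT_0006|SPC_0006	SPT_0006	SPC_0006	16C	ELD_P2	0	0.655254991192976	2.6210199647719	2.6210199647719	2596	980
SPT_0007|SPC_0007	SPT_0007	SPC_0007	16C	no_change	0	0.523665780610215	0.523665780610215	0.523665780610215	1651	1821
SPT_0008|SPC_0008	SPT_0008	SPC_0008	16C	no_change	0	0.969477640500901	0.969477640500901	0.969477640500901	1826	2571
SPT_0009|SPC_0009	SPT_0009	SPC_0009	16C	no_change	0	1.41702185170964	1.41702185170964	1.41702185170964	2571	798
SPT_0010|SPC_0010	SPT_0010	SPC_0010	16C	ELD_P2	0	0.826621379787273	3.30648551914909	3.30648551914909	855	2953
SPT_0011|SPC_0011	SPT_0011	SPC_0011	16C	ELD_P2	2.57452636103147	0.169967526531709	0.679870106126836	0.679870106126836	2124	2861
SPT_0012|SPC_0012	SPT_0012	SPC_0012	16C	transgressive_down	0	2.19116119322829	0.547790298307074	0.273895149153537	664	1815
SPT_0013|SPC_0013	SPT_0013	SPC_0013	16C	no_change	0	1.25123659010107	1.25123659010107	1.25123659010107	2957	1335
SPT_0014|SPC_0014	SPT_0014	SPC_0014	16C	ELD_P1	0	1.10090559372946	4.40362237491786	1.10090559372946	2402	1481
SPT_0015|SPC_0015	SPT_0015	SPC_0015	16C	no_change	0	0.447300332749273	0.447300332749273	0.447300332749273	1398	2693
SPT_0016|SPC_0016	SPT_0016	SPC_0016	16C	ELD_P2	0	2.94651844301452	0.736629610753631	0.736629610753631	1100	1871
SPT_0017|SPC_0017	SPT_0017	SPC_0017	16C	no_change	0	0.1229787327118	0.1229787327118	0.1229787327118	1806	2744
SPT_0018|SPC_0018	SPT_0018	SPC_0018	16C	additivity	2.16049980894538	2.45779750167539	9.83119000670156	6.14449375418848	1431	2039
SPT_0019|SPC_0019	SPT_0019	SPC_0019	16C	no_change	0	1.45520381756398	1.45520381756398	1.45520381756398	1496	2773
SPT_0020|SPC_0020	SPT_0020	SPC_0020	16C	no_change	0	1.02291897964805	1.02291897964805	1.02291897964805	2514	1226
SPT_0001|SPC_0001	SPT_0001	SPC_0001	4C	ELD_P2	0	1.02191819351257	4.08767277405028	4.08767277405028	2868	1120
SPT_0002|SPC_0002	SPT_0002	SPC_0002	4C	no_change	0	3.55890661809795	3.55890661809795	3.55890661809795	1676	2040
SPT_0003|SPC_0003	SPT_0003	SPC_0003	4C	no_change	-2.81604883953668	1.10568443632845	1.10568443632845	1.10568443632845	1597	1359
SPT_0004|SPC_0004	SPT_0004	SPC_0004	4C	ELD_P2	-2.92388867070197	2.35936483240382	0.589841208100955	0.589841208100955	1751	758
SPT_0005|SPC_0005	SPT_0005	SPC_0005	4C	no_change	0	1.76499508374177	1.76499508374177	1.76499508374177	1133	1837
SPT_0006|SPC_0006	SPT_0006	SPC_0006	4C	no_change	0	0.655254991192976	0.655254991192976	0.655254991192976	2596	980
SPT_0007|SPC_0007	SPT_0007	SPC_0007	4C	ELD_P2	0	0.523665780610215	2.09466312244086	2.09466312244086	1651	1821
SPT_0008|SPC_0008	SPT_0008	SPC_0008	4C	no_change	0	0.969477640500901	0.969477640500901	0.969477640500901	1826	2571
SPT_0009|SPC_0009	SPT_0009	SPC_0009	4C	ELD_P2	0	5.66808740683858	1.41702185170964	1.41702185170964	2571	798
SPT_0010|SPC_0010	SPT_0010	SPC_0010	4C	no_change	0	0.826621379787273	0.826621379787273	0.826621379787273	855	2953
SPT_0011|SPC_0011	SPT_0011	SPC_0011	4C	no_change	2.57452636103147	0.169967526531709	0.169967526531709	0.169967526531709	2124	2861
SPT_0012|SPC_0012	SPT_0012	SPC_0012	4C	no_change	0	0.547790298307074	0.547790298307074	0.547790298307074	664	1815
SPT_0013|SPC_0013	SPT_0013	SPC_0013	4C	transgressive_down	0	1.25123659010107	1.25123659010107	0.625618295050535	2957	1335
SPT_0014|SPC_0014	SPT_0014	SPC_0014	4C	transgressive_down	0	4.40362237491786	1.10090559372946	0.550452796864732	2402	1481
SPT_0015|SPC_0015	SPT_0015	SPC_0015	4C	no_change	0	0.447300332749273	0.447300332749273	0.447300332749273	1398	2693
SPT_0016|SPC_0016	SPT_0016	SPC_0016	4C	transgressive_down	0	0.736629610753631	0.736629610753631	0.368314805376816	1100	1871
SPT_0017|SPC_0017	SPT_0017	SPC_0017	4C	no_change	0	0.1229787327118	0.1229787327118	0.1229787327118	1806	2744
SPT_0018|SPC_0018	SPT_0018	SPC_0018	4C	no_change	2.16049980894538	2.45779750167539	2.45779750167539	2.45779750167539	1431	2039
SPT_0019|SPC_0019	SPT_0019	SPC_0019	4C	no_change	0	1.45520381756398	1.45520381756398	1.45520381756398	1496	2773
SPT_0020|SPC_0020	SPT_0020	SPC_0020	4C	no_change	0	1.02291897964805	1.02291897964805	1.02291897964805	2514	1226
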