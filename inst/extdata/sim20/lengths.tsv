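transcript_id	length
SPT_0001	2868
SPT_0002	1676
SPT_0003	1597
SPT_0004	1751
SPT_0005	1133
SPT_0006	2596
SPT_0007	1651
SPT_0008	1826
SPT_0009	2571
SPT_0010	855
SPT_0011	2124
SPT_0012	664
SPT_0013	2957
SPT_0014	2402
SPT_0015	1398
SPT_0016	1100
SPT_0017	1806
SPT_0018	1431
SPT_0019	1496
SPT_0020	2514
SPC_0001	1120
SPC_0002	2040
SPC_0003	1359
SPC_0004	758
SPC_0005	1837
SPC_0006	980
SPC_0007	1821
SPC_0008	2571
SPC_0009	798
SPC_0010	2953
SPC_0011	2861
SPC_0012	1815
SPC_0013	1335
SPC_0014	1481
SPC_0015	2693
SPC_0016	1871
SPC_0017	2744
SPC_0018	2039
SPC_0019	2773
SPC_0020	1226
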