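sample_id	lib_size
P1_30C_r1	10374681
P1_30C_r2	10561292
P1_30C_r3	9682341
P1_16C_r1	10338714
P1_16C_r2	10417242
P1_16C_r3	9723898
P1_4C_r1	10400901
P1_4C_r2	9450331
P1_4C_r3	9224132
P2_30C_r1	9410894
P2_30C_r2	10313203
P2_30C_r3	10021475
P2_16C_r1	9928316
P2_16C_r2	9927723
P2_16C_r3	9980698
P2_4C_r1	9682983
P2_4C_r2	10194357
P2_4C_r3	9255728
F1_30C_r1	10507117
F1_30C_r2	9813614
F1_30C_r3	10640217
F1_16C_r1	9537185
F1_16C_r2	10924238
F1_16C_r3	10469345
F1_4C_r1	9562472
F1_4C_r2	9661769
F1_4C_r3	9513015
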