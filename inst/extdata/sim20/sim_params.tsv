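key	value
n_pairs	20
n_replicates	3
conditions	30C,16C,4C
baseline_mean	500
dispersion	0.05
parental_fold	4
transgressive_factor	2
expr_sd	0.6
length_min	500
length_max	3000
lib_size	1e+07
depth_sd	0.05
seed	42
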