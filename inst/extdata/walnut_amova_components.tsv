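source	df	SS	sigma2	percent
among_groups	5	424.430	0.36063	12.83
within_groups	1426	3495.415	2.45120	87.17
total	1431	3919.844	2.81184	NA
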