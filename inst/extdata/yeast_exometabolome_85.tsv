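metabolite	experiment	gene_expression	standard_fba	fitted_fba	gimme	imat
Ethanol	13.0	16.2	0	0	0	0
CO2	21.0	20.1	25.0	21.0	16.0	32.2
Glycerol	2.17	0.126	0	0	0	0
Acetate	0.239	0.00911	0	0	0	0
Trehalose	0.0215	0.0220	0	0	0	0
Lactate	0.00609	0.0176	0	0	0	0
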