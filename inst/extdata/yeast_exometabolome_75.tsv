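metabolite	experiment	gene_expression	standard_fba	fitted_fba	gimme	imat
Ethanol	23.8	25.7	0	0	0	0
CO2	22.7	31.5	37.6	22.7	31.5	48.5
Glycerol	3.54	0	0	0	0	0
Acetate	0.311	0.016	0	0	0	0
Trehalose	0.0356	0.0301	0	0	0	0
Lactate	0.00873	0.0301	0	0	0	0
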