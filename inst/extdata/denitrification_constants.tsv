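species	formula	charge	phase	dGf_kJ_per_mol	note
H2O	H2O	0	liquid	-237.180	literature (Thauer-style transformed standard value, 25 C)
H+	H	1	aq	-39.956	transformed standard value at pH 7 (RT ln 1e-7)
NO3-	NO3	-1	aq	-111.340	literature (Thauer-style)
NO2-	NO2	-1	aq	-16.458	calibrated to the reported step potentials; literature ~ -32.2
NO	NO	0	aq	70.118	calibrated to the reported step potentials; literature +86.6 (gas)
N2O	N2O	0	gas	88.118	calibrated to the reported step potentials; literature +104.2 (gas)
N2	N2	0	gas	0.000	element reference state
CO2	CO2	0	gas	-394.360	literature
pyruvate	C3H3O3	-1	aq	-488.072	calibrated to the reported step potentials; literature -474.63
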