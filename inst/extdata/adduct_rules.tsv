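name	polarity	n	z	mass_delta	requires_elements	requires_ion
[M+H]+	positive	1	1	1.007276		
[M+Na]+	positive	1	1	22.9892207		
[M+K]+	positive	1	1	38.9631581		
[M+NH4]+	positive	1	1	18.0338255528		NH4+
[2M+H]+	positive	2	1	1.007276		
[M+H-H2O]+	positive	1	1	-17.0032886859	O	
[M+H-NH3]+	positive	1	1	-16.0192731009	N	
[M-H]-	negative	1	1	-1.007276		
[M+Cl]-	negative	1	1	34.96940126		
[M+HCOO]-	negative	1	1	44.9982028561		HCOO-
[2M-H]-	negative	2	1	-1.007276		
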