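family_id	subject_id	sex	age	aat_level	genotype	fev1_pct_pred	smoking	affected
3	AWI	F	67	18	ZZ	94	non_smoker	0
3	AWJ	M	65	43	ZZ	106	non_smoker	0
3	AWK	M	60	22	ZZ	25	ex_smoker	1
185	AWL	F	73	37	ZZ	57	non_smoker	1
185	AWM	F	71	36	ZZ	85	non_smoker	0
237	BIR	F	53	28	ZZ	102	non_smoker	1
237	BQ0	F	43	35	ZZ	100	non_smoker	0
114	BIP	M	50	23.3	Z/Q0	32	ex_smoker	1
114	BIQ	F	47	20	Z/Q0	99	non_smoker	0
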