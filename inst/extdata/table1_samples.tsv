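group	sample_id	n_cells	n_functional	pct_functional	pct_single	pct_multiple
thymus_total	T01	5208	1668	32.028	85.012	14.988
thymus_total	T02	NA	NA	60.533	59.940	40.060
thymus_total	T03	NA	NA	42.478	81.942	18.058
thymus_total	T04	NA	NA	47.336	83.510	16.490
thymus_total	T05	NA	NA	64.660	89.945	10.055
thymus_cd45pos	P01	NA	NA	39.765	82.811	17.189
thymus_cd45pos	P02	NA	NA	41.650	83.576	16.424
thymus_cd45pos	P03	NA	NA	38.304	83.865	16.135
thymus_cd45pos	P04	NA	NA	36.636	86.792	13.208
thymus_cd45pos	P05	NA	NA	42.545	83.429	16.571
thymus_cd45neg	N01	NA	NA	4.848	89.011	10.989
thymus_cd45neg	N02	NA	NA	16.943	90.909	9.091
frail	R01	NA	NA	62.684	91.463	8.537
frail	R02	NA	NA	71.702	93.961	6.039
frail	R03	NA	NA	66.425	89.481	10.519
frail	R04	NA	NA	69.623	88.951	11.049
frail	R05	NA	NA	73.367	92.629	7.371
young	C01	NA	NA	63.381	90.562	9.438
young	C02	NA	NA	54.115	89.920	10.080
young	C03	NA	NA	62.046	89.629	10.371
old	L01	NA	NA	62.493	86.227	13.773
old	L02	NA	NA	65.988	88.042	11.958
old	L03	NA	NA	65.018	87.205	12.795
old	L04	NA	NA	62.960	85.569	14.431
old	L05	NA	NA	59.472	84.619	15.381
mouse_ln	LN1	NA	NA	74.500	79.616	20.384
mouse_ln	LN2	NA	NA	72.270	79.897	20.103
mouse_ln	LN3	NA	NA	62.155	79.502	20.498
mouse_spleen	S1	NA	NA	62.147	79.502	20.498
mouse_spleen	S2	NA	NA	74.482	81.171	18.829
mouse_spleen	S3	NA	NA	73.119	81.629	18.371
mouse_blood	B1	NA	NA	70.545	82.895	17.105
mouse_blood	B2	NA	NA	73.200	81.695	18.305
mouse_blood	B3	NA	NA	67.113	81.595	18.405
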