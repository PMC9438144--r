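feature_id	fc_signed	p_raw	avg_rank_reported
hsa-miR-5189-3p	2,59	0,0057	1
hsa-miR-96-5p	-2,40	0,0032	2
hsa-miR-3613-5p	2,55	0,0101	3
hsa-miR-99a-3p	2,37	0,0079	4
hsa-miR-542-3p	2,40	0,0164	5
hsa-miR-6803-3p	2,19	0,0162	6
hsa-miR-6731-3p	-2,14	0,0084	7
hsa-miR-577	-2,17	0,0200	8
hsa-miR-95-3p	-2,06	0,0184	9
hsa-miR-556-3p	-2,18	0,0228	10
hsa-miR-412-5p	-2,36	0,0290	11
hsa-miR-5701	-2,24	0,0263	12
hsa-miR-3064-5p	2,10	0,0247	13
hsa-miR-196a-5p	-2,55	0,0450	14
hsa-miR-5189-5p	1,93	0,0222	15
hsa-let-7i-3p	-1,82	0,0067	16
hsa-miR-1277-5p	2,07	0,0402	17
hsa-miR-29b-3p	-1,85	0,0214	18
hsa-miR-4676-3p	1,87	0,0261	19
hsa-miR-548j-3p	1,91	0,0453	20
hsa-miR-1260b	1,78	0,0361	24
hsa-miR-326	1,62	0,0027	26
hsa-miR-3174	1,79	0,0480	27
hsa-miR-210-3p	1,77	0,0461	31
hsa-miR-32-5p	-1,65	0,0373	34
hsa-miR-342-3p	-1,60	0,0307	40
hsa-miR-3607-3p	-1,59	0,0381	44
hsa-miR-142-5p	-1,54	0,0239	54
hsa-miR-192-5p	-1,56	0,0440	57
hsa-miR-155-5p	-1,43	0,0186	74
hsa-let-7g-5p	-1,43	0,0351	76
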