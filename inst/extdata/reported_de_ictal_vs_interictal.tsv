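feature_id	fc_signed	p_raw	avg_rank_reported
hsa-miR-3202	2,94	0,0014	1
hsa-miR-7855-5p	-2,69	0,0033	2
hsa-miR-6770-3p	2,90	0,0135	3
hsa-miR-1538	-2,22	0,0023	4
hsa-miR-409-5p	-2,57	0,0072	5
hsa-miR-501-3p	-2,16	0,0014	6
hsa-miR-1299	3,53	0,0248	7
hsa-miR-1271-5p	-2,60	0,0187	8
hsa-miR-4687-3p	-2,21	0,0217	9
hsa-miR-4743-5p	-2,07	0,0135	10
hsa-miR-1277-5p	2,08	0,0184	11
hsa-miR-3180-3p	2,51	0,0351	12
hsa-miR-4646-5p	-2,18	0,0311	13
hsa-miR-5581-3p	2,14	0,0251	14
hsa-miR-6882-5p	2,11	0,0257	15
hsa-miR-449a	1,94	0,0332	16
hsa-miR-4473	2,01	0,0439	17
hsa-miR-4775	1,96	0,0422	18
hsa-miR-33b-3p	-1,92	0,0411	20
hsa-miR-99b-5p	-1,84	0,0242	21
hsa-miR-1270	1,87	0,0328	22
hsa-miR-18b-5p	1,94	0,0463	23
hsa-miR-6864-5p	1,90	0,0374	24
hsa-miR-211-5p	1,91	0,0493	25
hsa-miR-590-3p	1,82	0,0392	31
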