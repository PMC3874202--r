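domain	locus	fraction	fmoles
E-pro	domain	CE	1234
E-pro	domain	P	642
E-pro	domain	SUP	611
E-pro	domain	FT_igg	134
E-pro	domain	E_igg	161
E-pro	domain	B_igg	3
5S	domain	CE	3521
5S	domain	P	2320
5S	domain	SUP	1398
5S	domain	FT_igg	717
5S	domain	E_igg	248
5S	domain	B_igg	72
ARS	domain	CE	4235
ARS	domain	P	1716
ARS	domain	SUP	2612
ARS	domain	FT_igg	757
ARS	domain	E_igg	534
ARS	domain	B_igg	69
35S	domain	CE	2988
35S	domain	P	2102
35S	domain	SUP	446
35S	domain	FT_igg	131
35S	domain	E_igg	53
35S	domain	B_igg	74
PHO5	domain	CE	1678
PHO5	domain	P	439
PHO5	domain	SUP	632
PHO5	domain	FT_igg	224
PHO5	domain	E_igg	191
PHO5	domain	B_igg	16
PHO5	domain	FT_cam	119
PHO5	domain	E_cam	50
PHO5	domain	B_cam	6
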