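module	set	nodes	edges	up	down
Brown	down	1676	1149157	0	672
Coral1	up	1173	482242	386	0
Black	up	875	335415	157	2
Darkorange	up	683	156692	270	0
Darkolivegreen4	down	615	136748	0	144
Darkred	up	607	124171	170	0
Coral2	none	375	45234	16	10
Grey60	down	370	53283	0	130
Lightcyan1	down	332	35644	0	27
Brown2	none	291	28624	0	6
Navajowhite2	none	159	8570	5	8
Bisque4	none	135	6022	10	0
Royalblue	none	117	4724	0	22
Darkgreen	none	116	4704	0	1
Yellowgreen	none	91	895	0	0
Plum1	none	85	1537	2	3
Ivory	none	79	1641	0	0
Brown4	none	72	743	6	0
Darkslateblue	none	71	1258	0	0
Thistle2	none	66	1552	0	4
Lavenderblush3	none	62	1464	0	1
Darkseagreen4	none	59	1464	0	0
Orangered3	none	52	1143	4	0
Lightsteelblue	none	49	579	2	3
Lightcoral	none	48	470	3	0
Firebrick4	none	45	548	0	0
Blue2	none	43	378	3	0
Darkviolet	none	41	671	2	0
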