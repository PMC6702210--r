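node	parent	haplogroup	mutations
rCRS	NA	rCRS	
M1a1c	M	M1a1c	3384,7094,11215
H	rCRS	H	2706,11719,12705,14766,16223
T1	J1b	T1	11215,16294
M3C1	M	M3C1	482,16294
M2c	M	M2c	4216
M3c2	M3	M3c2	482
U4b2	rCRS	U4b2	8701,11467
M3a2	M3c2	M3a2	5783,10727
U2b2	U.1	U2b2	1811,1888,2706,8701,12705
M3	M	M3	16126
U	U.1	U	3714,8701,13188
M4''67	M	M4''67	12007
H1	H	H1	3010,9540
N1b	rCRS	N1b	1598,8701,9540
H1.1	H12	H1	3010,3434,5301,11719
N	H.3	N	16223
H.1	M	H	482,4703
M3a1	N2	M3a1	9540,12705
HV	rCRS	HV	207,709,8701,9540,16126
N2	rCRS	N2	8701,11719,14766,16223
HV.1	M	HV	8701,9540,12361
N1a1b1	M6	N1a1b1	7094,7859,8701,11215,13104,16172,16223
M5	M	M5	709,8502,11083,12810,16274
M2a	M6	M2a	709
M5.1	rCRS	M5	8701,9540,12705,16223
R2	M3	R2	5301
M6	M	M6	1888
M	rCRS	M	15043
M.1	M4''67	M	3714,5301,13104,16223,16294
M4''67.1	U2b2	M4''67	9540
M9a2	M5.1	M9a2	1811,16126
U2e3	K	U2e3	9540,12705
U2e	X	U2e	6371
H.2	rCRS	H	2706,9540,12705
T1.1	N	T1	4491,15043,16126
J1b	rCRS	J1b	709,1888,4216,8697,8701,9540,11251,12633,14905,15452,15607,16126,16223
M30	T	M30	3010,11251,12406,15452,16069,16612
HV.2	M3c2	HV	4703
H.3	H.2	H	8701,11719,14766
M2a1	rCRS	M2a1	207,4703,15670
H12	H.2	H12	16223
U.1	rCRS	U	11467,12308
X	rCRS	X	6221,8701,9540
M6.1	M	M6	5082,5301
H1.2	H1	H1	8701
M24	M	M24	13359,15607
J1b1a1	T	J1b1a1	3010,11251,12007,12612,15452,16069,16172
D4	M	D4	3010,5178,8414
U2a1	U2e3	U2a1	10609
K	U.1	K	1811,8701,16223
U7	U2e3	U7	14569
H.4	N	H	709
T	M5.1	T	4216,16126
U.2	U.1	U	3741
JT	rCRS	JT	12308,16126
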