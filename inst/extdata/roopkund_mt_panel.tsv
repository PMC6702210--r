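skeletal_code	mt_hg_pcr	mutations	sample_id	mt_hg_capture	group
R01	M1a1c	15043,3384,7094,11215	I2868	M33d	Roopkund_A
R02	H	2706,12705,11719,14766,16223	I2869	H6b1	Roopkund_B
R03	T1	16294,16223,12633,11251,15452,8701,15607,1888,14905,11215,9540,8697,16126,12633,4216,709	I2870	T1a	Roopkund_B
R04	M3C1	15043,482,16294	I2871	M3c1a	Roopkund_A
R05	M2c	15043,4216	NA	NA	NA
R06	M3c2	15043,16126,482	I2872	M3c2	Roopkund_A
R07	U4b2	11467,8701	NA	NA	NA
R08	M3a2	15043,16126,482,5783,10727	I3342	M3a2	Roopkund_A
R09	U2b2	1888,11467,12308,2706,12705,8701,1811	NA	NA	NA
R10	M3	15043,16126	I3343	M3	Roopkund_A
R11	U	11467,12308,8701,3714,13188	I3344	U2c1	Roopkund_A
R12	M4''67	12007,15043	NA	NA	NA
R13	H1	16223,14766,11719,12705,9540,3010,2706	I3345	H1	Roopkund_B
R14	N1b	9540,8701,1598	NA	NA	NA
R15	NA	NA	I3346	M30c	Roopkund_A
R16	H1	16223,11719,5301,3434,12705,9540,3010,2706	I3348	H1c	Roopkund_B
R17	NA	16223,14766,11719,8701,12705,9540,2706	I3349	M5a	Roopkund_A
R18	H	15043,482,4703	I3350	H60a	Roopkund_B
R19	M3a1	9540,12705,8701,11719,14766,16223	I3351	M4	Roopkund_A
R20	HV	9540,12705,8701,11719,14766,16223	I3352	HV14	Roopkund_A
R21	HV	709,16126,207,9540,8701	NA	NA	NA
R22	N2	8701,11719,14766,16223	I3401	W1	Roopkund_B
R23	HV	15043,9540,8701,12361	NA	NA	NA
R24	N1a1b1	1888,15043,7094,7859,11215,8701,16172,13104,16223	NA	NA	NA
R25	M5	709,11083,15043,8502,16274,12810	I3402	U1a1	Roopkund_A
R26	M2a	709,1888,15043	NA	NA	NA
R28	M5	9540,12705,8701,16223	NA	NA	NA
R29	R2	15043,16126,5301	NA	NA	NA
R31	M6	1888,15043	NA	NA	NA
R32	M5	15043	NA	NA	NA
R33	M	12007,15043,5301,3714,13104,16223,16294	NA	NA	NA
R34	M4''67	1888,11467,12308,2706,9540,12705,8701,1811	NA	NA	NA
R35	U2b	15043	NA	NA	NA
R36	M9a2	16126,9540,12705,8701,1811,16223	NA	NA	NA
R37	HV	11467,12308,9540,12705,8701,1811,16223	NA	NA	NA
R38	U2e	6221,6371,9540,8701	NA	NA	NA
R39	N	2706,9540,12705,8701,11719,14766,16223	I3403	X2d	Roopkund_B
R40	H	2706,9540,12705	I3404	H12	Roopkund_B
R41	T1	16223,14766,11719,8701,12705,9540,2706,16126,15043,4491	NA	NA	NA
R42	J1b	709,1888,4216,12633,16126,8697,9540,14905,15607,8701,15452,11251,12633,16223	I3405	J1b	Roopkund_B
R43	M30	4216,16126,3010,9540,16612,12705,8701,12406,15452,16069,11251,16223	I3406	M30	Roopkund_A
R44	M3a1	12007,15043	I3407	M3a1	Roopkund_A
R45	NA	NA	I6934	NA	Roopkund_A
R46	HV	15043,16126,482,4703	I6935	NA	Roopkund_B
R47	H	2706,9540,12705,8701,11719,14766	NA	NA	NA
R48	M2a1	15670,207,4703	I6936	H1	Roopkund_B
R49	H12	2706,9540,12705,16223	I6937	H12a	Roopkund_B
R50	U4	11467,12308	NA	NA	NA
R51	X	6221,9540,8701	I6938	X2p	Roopkund_A
R52	M6	15043,5082,5301	NA	NA	NA
R53	H1	2706,3010,9540,12705,8701,11719,14766,16223	I6939	H1	Roopkund_B
R54	M24	15043,13359,15607	I6940	M24a	Roopkund_C
R55	J1b1a1	4216,12007,16126,3010,9540,12612,12705,8701,15452,16069,16172,11251,16223	I6941	J1b1a1	Roopkund_A
R56	M	15043	NA	NA	NA
R57	P4b1	12007,15043	I6942	R30b2a	Roopkund_A
R59	D4	15043,3010,5178,8414	NA	NA	NA
R60	M4''67	12007,15043	NA	NA	NA
R61	M3a1	15043,16126,482,4703	I6943	M3a1	Roopkund_A
R62	U2e3	16223,1811,8701,12705,9540,12308,11467	I6944	U4d3	Roopkund_A
R63	U2e3	11467,12308,9540,12705,8701,1811,16223	NA	NA	NA
R64	M4''67	12007,15043	I6945	M30+16234	Roopkund_A
R65	U2a1	11467,12308,9540,12705,8701,10609,1811,16223	I6946	U8b1a1	Roopkund_A
R66	K	11467,12308,8701,1811,16223	I6947	K1a	Roopkund_B
R67	M	15043	NA	NA	NA
R68	U7	11467,12308,9540,12705,8701,14569,1811,16223	I7035	U7a2	Roopkund_A
R69	H	709,2706,9540,12705,8701,11719,14766,16223	I7036	H13a2a	Roopkund_A
R72	T	4216,16126,9540,12705,8701,16223	NA	NA	NA
R73	U	3741,12308,11467	NA	NA	NA
R74	U	11467,12308	NA	NA	NA
R76	JT	16126,12308	NA	NA	NA
R77	U	11467,12308	NA	NA	NA
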