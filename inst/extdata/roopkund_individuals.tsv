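sample_id	skeletal_code	n_libraries	group	sex	mt_hg_pcr	mt_hg_capture	y_haplogroup	y_caution	endogenous	coverage	n_snps	damage_rate	x_contamination	mt_match_rate	cal_from	cal_to	cal_open	d13c	d13c_alt	d15n	d15n_alt
I2868	R01	3	Roopkund_A	M	M1a1c	M33d	H1a2a1	FALSE	0.014	0.868	570995	0.071	NA	0.996	890	982	FALSE	-19.40	NA	7.69	NA
I2871	R04	4	Roopkund_A	F	M3C1	M3c1a	NA	NA	0.005	0.579	441880	0.049	NA	0.997	773	940	FALSE	-16.32	NA	9.77	NA
I2872	R06	4	Roopkund_A	F	M3c2	M3c2	NA	NA	0.003	0.199	196393	0.046	NA	1.000	773	940	FALSE	-19.00	NA	9.24	NA
I3342	R08	1	Roopkund_A	M	M3a2	M3a2	H1a1d2	FALSE	0.007	0.577	403739	0.047	0.013	1.000	773	940	FALSE	-18.94	-18.88	9.69	9.85
I3343	R10	1	Roopkund_A	F	M3	M3	NA	NA	0.006	0.223	203058	0.055	NA	1.000	773	890	FALSE	-19.74	NA	9.99	NA
I3344	R11	1	Roopkund_A	F	U	U2c1	NA	NA	0.003	0.105	111184	0.049	NA	1.000	775	890	FALSE	-11.45	NA	8.71	NA
I3346	R15	1	Roopkund_A	M	NA	M30c	E1b1b1	FALSE	0.004	0.304	271560	0.065	0.008	1.000	717	889	FALSE	-15.93	NA	10.29	NA
I3349	R17	1	Roopkund_A	F	NA	M5a	NA	NA	0.004	0.133	136268	0.059	NA	0.998	770	945	FALSE	-10.74	NA	9.58	NA
I3351	R19	1	Roopkund_A	M	M3a1	M4	J	TRUE	0.006	0.044	50278	0.057	NA	0.994	770	887	FALSE	-14.47	-14.42	9.39	9.63
I3352	R20	1	Roopkund_A	M	HV	HV14	R2a3a2b2c	FALSE	0.017	1.476	591844	0.041	0.004	0.998	689	876	FALSE	-16.27	NA	9.13	NA
I3402	R25	1	Roopkund_A	M	M5	U1a1	H3b	FALSE	0.002	0.118	125762	0.036	NA	1.000	770	887	FALSE	-17.18	NA	10.36	NA
I3406	R43	1	Roopkund_A	M	M30	M30	J2a1	FALSE	0.016	0.295	251527	0.045	NA	0.999	885	980	FALSE	-18.46	-18.07	7.95	8.23
I3407	R44	1	Roopkund_A	M	M3a1	M3a1	H1a1d2	FALSE	0.011	0.105	110441	0.045	NA	0.976	775	961	FALSE	-18.22	-18.27	9.85	9.69
I6934	R45	1	Roopkund_A	F	NA	NA	NA	NA	0.034	0.861	521678	0.033	NA	1.000	773	890	FALSE	-16.53	NA	8.41	NA
I6938	R51	1	Roopkund_A	F	X	X2p	NA	NA	0.011	0.481	405124	0.058	NA	0.999	694	875	FALSE	-18.62	-18.16	8.25	8.40
I6941	R55	1	Roopkund_A	M	J1b1a1	J1b1a1	NA	NA	0.009	0.590	452228	0.044	-0.001	1.000	894	985	FALSE	-10.13	NA	8.90	NA
I6942	R57	1	Roopkund_A	M	P4b1	R30b2a	NA	NA	0.008	0.602	470065	0.047	-0.001	1.000	770	887	FALSE	-18.66	-18.42	8.22	8.33
I6943	R61	1	Roopkund_A	M	M3a1	M3a1	NA	NA	0.007	0.133	145489	0.064	NA	0.999	675	769	FALSE	-10.10	NA	8.24	NA
I6944	R62	1	Roopkund_A	F	U2e3	U4d3	NA	NA	0.009	0.340	313369	0.055	NA	1.000	726	885	FALSE	-18.00	-18.10	8.58	7.90
I6945	R64	1	Roopkund_A	F	M4''67	M30+16234	NA	NA	0.007	0.035	40150	0.045	NA	0.997	687	870	FALSE	-17.08	NA	8.92	NA
I6946	R65	1	Roopkund_A	M	U2a1	U8b1a1	NA	NA	0.005	0.349	328001	0.055	-0.002	1.000	773	890	FALSE	-10.21	NA	10.09	NA
I7035	R68	1	Roopkund_A	F	U7	U7a2	NA	NA	0.008	0.565	446699	0.041	NA	0.999	889	971	FALSE	-16.74	-16.50	10.19	10.21
I7036	R69	1	Roopkund_A	M	H	H13a2a	NA	NA	0.009	0.370	342426	0.057	0.005	1.000	778	988	FALSE	-18.59	NA	9.33	NA
I2869	R02	4	Roopkund_B	M	H	H6b1	J1a3a	FALSE	0.036	0.782	578890	0.057	NA	0.997	1668	1945	FALSE	-18.69	NA	10.89	NA
I2870	R03	2	Roopkund_B	F	T1	T1a	NA	NA	0.024	0.028	31880	0.039	NA	0.938	1706	1915	FALSE	-18.67	NA	11.15	NA
I3345	R13	1	Roopkund_B	M	H1	H1	R1a1a1b1a2b	FALSE	0.056	1.547	706651	0.059	0.002	0.997	1681	1939	FALSE	-18.93	NA	10.76	NA
I3348	R16	1	Roopkund_B	F	H1	H1c	NA	NA	0.006	0.409	352584	0.051	NA	1.000	1682	1932	FALSE	-19.23	NA	9.21	NA
I3350	R18	1	Roopkund_B	M	H	H60a	G2a2b2a1a1c1a2	FALSE	0.031	1.349	614489	0.069	0.004	0.995	1675	1943	FALSE	-19.41	-19.10	9.95	10.02
I3401	R22	1	Roopkund_B	M	N2	W1	R1b1a	TRUE	0.005	0.049	56291	0.056	NA	1.000	NA	NA	NA	NA	NA	NA	NA
I3403	R39	1	Roopkund_B	M	N	X2d	T1a2	FALSE	0.018	0.492	379935	0.035	0.005	0.995	1691	1925	FALSE	-18.60	-18.19	10.77	10.61
I3404	R40	1	Roopkund_B	M	H	H12	E1b1b1b2	FALSE	0.040	1.077	541763	0.041	0.006	0.997	1706	1915	FALSE	-19.23	NA	9.62	NA
I3405	R42	1	Roopkund_B	F	J1b	J1b	NA	NA	0.019	0.514	346216	0.031	NA	1.000	1656	NA	TRUE	-19.72	NA	10.07	NA
I6935	R46	1	Roopkund_B	F	HV	NA	NA	NA	0.017	0.627	524922	0.060	NA	0.997	1668	1945	FALSE	-18.97	NA	8.91	NA
I6936	R48	1	Roopkund_B	M	M2a1	H1	NA	NA	0.034	1.371	728448	0.043	0.005	0.998	1681	1939	FALSE	-18.79	NA	9.79	NA
I6937	R49	1	Roopkund_B	F	H12	H12a	NA	NA	0.026	0.837	584656	0.035	NA	1.000	1661	NA	TRUE	-19.56	NA	8.93	NA
I6939	R53	1	Roopkund_B	M	H1	H1	NA	NA	0.008	0.605	476797	0.037	0.006	0.999	1680	1939	FALSE	-19.22	NA	10.46	NA
I6947	R66	1	Roopkund_B	M	K	K1a	NA	NA	0.050	0.026	30592	0.025	NA	0.940	1675	1943	FALSE	-18.95	NA	9.96	NA
I6940	R54	1	Roopkund_C	M	M24	M24a	O1b1a1a1b	FALSE	0.011	0.489	419098	0.047	0.022	1.000	1653	NA	TRUE	-19.25	-18.32	9.98	9.74
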