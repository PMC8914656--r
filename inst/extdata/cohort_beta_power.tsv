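subject	condition	Fp1	Fp2	C3	C4	O1	O2
1	ADAS1	2.33	1.99	3.27	3.97	3.34	4.68
2	ADAS1	4.63	5.99	6.69	7.12	7.66	6.90
3	ADAS1	2.39	1.68	3.54	2.90	4.37	5.05
4	ADAS1	2.91	3.60	4.83	3.58	3.53	4.25
5	ADAS1	2.39	1.95	5.34	5.35	7.40	6.46
6	ADAS1	1.66	1.51	4.18	2.72	3.10	4.63
7	ADAS1	2.12	1.53	6.42	8.48	3.98	5.24
8	ADAS1	2.33	2.08	3.92	3.26	3.14	4.10
9	ADAS1	2.04	1.27	3.39	3.17	7.11	9.03
10	ADAS1	1.20	4.37	5.59	3.92	3.99	4.08
1	ADAS2	2.56	2.73	4.67	3.91	9.06	6.63
2	ADAS2	4.86	5.81	5.40	6.22	7.67	9.77
3	ADAS2	3.21	3.05	5.71	4.85	3.91	4.86
4	ADAS2	4.90	4.24	8.55	4.73	5.19	5.55
5	ADAS2	2.45	2.05	6.30	5.42	8.70	6.31
6	ADAS2	1.93	1.61	4.17	3.67	4.37	7.10
7	ADAS2	7.14	5.65	10.68	15.81	6.45	6.05
8	ADAS2	3.75	3.86	6.24	3.62	3.64	17.19
9	ADAS2	2.54	1.58	4.17	3.28	10.83	12.94
10	ADAS2	1.93	5.94	5.34	5.95	7.07	6.37
1	Manual	2.26	3.13	10.30	4.42	7.41	8.29
2	Manual	2.53	2.58	6.80	5.72	5.14	8.71
3	Manual	9.64	14.93	22.75	31.55	10.73	13.89
4	Manual	2.38	1.41	9.11	7.21	6.45	6.07
5	Manual	3.93	3.27	8.55	7.16	11.28	10.41
6	Manual	1.33	1.41	4.25	2.98	4.04	7.09
7	Manual	2.84	2.38	5.99	6.92	4.61	8.38
8	Manual	3.98	3.46	4.44	4.34	4.45	7.10
9	Manual	1.81	1.59	4.12	2.88	11.24	11.07
10	Manual	1.88	7.55	6.51	3.98	4.52	5.83
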