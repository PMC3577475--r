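property	accession	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
h	KYTJ820101	1.8	2.5	-3.5	-3.5	2.8	-0.4	-3.2	4.5	-3.9	3.8	1.9	-3.5	-1.6	-3.5	-4.5	-0.8	-0.7	4.2	-0.9	-1.3
M_v	GRAR740103	31	55	54	83	132	3	96	111	119	111	105	56	32.5	85	124	32	61	84	170	136
p	GRAR740102	8.1	5.5	13.0	12.3	5.2	9.0	10.4	5.2	11.3	4.9	5.7	11.6	8.0	10.5	10.5	9.2	8.6	5.9	5.4	6.2
c	GRAR740101	0	2.75	1.38	0.92	0	0.74	0.58	0	0.33	0	0	1.33	0.39	0.89	0.65	1.42	0.71	0	0.13	0.20
pH_i	ZIMJ680104	6.00	5.05	2.77	3.22	5.48	5.97	7.59	6.02	9.74	5.98	5.74	5.41	6.30	5.65	10.76	5.68	5.66	5.96	5.89	5.66
M_w	FASG760101	89.09	121.15	133.10	147.13	165.19	75.07	155.16	131.17	146.19	131.17	149.21	132.12	115.13	146.15	174.20	105.09	119.12	117.15	204.24	181.19
V^0	COHE430101	0.75	0.61	0.60	0.66	0.77	0.64	0.67	0.90	0.82	0.90	0.75	0.61	0.76	0.67	0.70	0.68	0.70	0.86	0.74	0.71
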