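cid	mf	mw	C	H	O	P	S	Zn	N	Cl	R3N	ROH	RCOR	RCOOH	RCOOR	ROR	rings	aromatics
4632	C14H12O3	228.24	14	12	3	0	0	0	0	0	0	1	1	0	0	1	2	2
8569	C14H12O4	244.24	14	12	4	0	0	0	0	0	0	2	1	0	0	1	2	2
8571	C13H10O5	246.22	13	10	5	0	0	0	0	0	0	4	1	0	0	0	2	2
8572	C13H10O3	214.21	13	10	3	0	0	0	0	0	0	2	1	0	0	0	2	2
11178	C36H70O4Zn	632.35	36	70	4	0	0	1	0	0	0	0	0	2	0	0	0	0
12738	C42H82O4S	683.16	42	82	4	0	1	0	0	0	0	0	0	0	2	0	0	0
15797	C21H26O3	326.42	21	26	3	0	0	0	0	0	0	1	1	0	0	1	2	2
16386	C35H62O3	530.86	35	62	3	0	0	0	0	0	0	1	0	0	1	0	1	1
17113	C13H11N3O	225.24	13	11	1	0	0	0	3	0	0	1	0	0	0	0	3	3
24667	C22H32O4	360.48	22	32	4	0	0	0	0	0	0	2	0	0	0	2	2	2
31250	C30H58O4S	514.84	30	58	4	0	1	0	0	0	0	0	0	0	2	0	0	0
31404	C15H24O	220.35	15	24	1	0	0	0	0	0	0	1	0	0	0	0	1	1
62485	C20H25N3O	323.43	20	25	1	0	0	0	3	0	0	1	0	0	0	0	3	3
62531	C17H18ClN3O	315.79	17	18	1	0	0	0	3	1	0	1	0	0	0	0	3	3
64819	C73H108O12	1177.63	73	108	12	0	0	0	0	0	0	4	0	0	4	0	4	4
70355	C13H16O2	204.26	13	16	2	0	0	0	0	0	0	1	1	0	0	0	2	1
77470	C20H24ClN3O	357.88	20	24	1	0	0	0	3	1	0	1	0	0	0	0	3	3
90571	C16H16O3	256.29	16	16	3	0	0	0	0	0	0	0	1	0	0	2	2	2
91601	C42H63O3P	646.92	42	63	3	1	0	0	0	0	0	0	0	0	0	0	3	3
93481	C20H23N3O3	353.41	20	23	3	0	0	0	3	0	0	1	0	0	1	0	3	3
112412	C30H29N3O	447.57	30	29	1	0	0	0	3	0	0	1	0	0	0	0	5	5
172473	C15H29NO6	319.39	15	29	6	0	0	0	1	0	1	2	0	2	0	0	1	0
3601357	C35H54O6P2	632.75	35	54	6	2	0	0	0	0	0	0	0	0	0	0	4	2
4992761	C27H27N3O2	425.52	27	27	2	0	0	0	3	0	0	1	0	0	0	1	4	4
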