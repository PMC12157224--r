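type	description	logp	mr
C.sp3.het.hi	sp3 C, >=2 H, bonded to N/O/P/S/halogen	-0.2035	2.753
C.sp3.het.lo	sp3 C, <=1 H, bonded to N/O/P/S/halogen	-0.2051	2.731
C.sp3.ar.h3	sp3 CH3 on aromatic ring	0.0845	2.464
C.sp3.ar.h2	sp3 CH2 on aromatic ring	-0.0516	2.488
C.sp3.ar.h1	sp3 CH on aromatic ring	0.1193	2.582
C.sp3.ar.h0	sp3 quaternary C on aromatic ring	-0.0967	2.576
C.sp3.hi	sp3 C, >=2 H, only C/H neighbors	0.1441	2.503
C.sp3.lo	sp3 C, <=1 H, only C/H neighbors	0.0000	2.433
C.hetdouble	C double/triple-bonded to a heteroatom (carbonyl C)	-0.2783	5.007
C.sp2.ar	sp2 C=C carbon substituted by an aromatic ring	0.2640	4.305
C.sp2	sp2 C=C carbon	0.1551	3.513
C.sp	sp carbon (triple bond)	0.0017	3.888
c.fused	aromatic C with three aromatic bonds (ring fusion)	0.2955	4.346
c.oxy	aromatic C bonded to O	0.5437	3.853
c.amine	aromatic C bonded to aliphatic N	0.4619	4.067
c.arsub	aromatic C single-bonded to an aromatic atom	0.2713	3.904
c.halo	aromatic C bonded to halogen	0.2450	3.564
c.alkyl	aromatic C bonded to aliphatic C	0.1360	3.509
c.h	aromatic CH	0.1581	3.350
n.aromatic	aromatic N	-0.3239	2.202
N.primary	aliphatic NH2	-1.0190	2.262
N.primary.ar	aryl NH2 (aniline)	-1.0270	2.827
N.secondary	aliphatic NH	-0.7096	2.173
N.secondary.ar	aryl NH	-0.5188	3.000
N.tertiary	aliphatic N	-0.3187	1.839
N.tertiary.ar	aryl tertiary N	-0.4458	2.819
O.carboxylate	carboxylate O-	-1.3260	0.000
O.hydroxyl	hydroxyl O (alcohol, phenol, acid OH)	-0.2893	0.8238
O.ether.ar	ether O bonded to an aromatic ring or to P	-0.4195	1.182
O.ether	aliphatic ether / ester O	-0.0684	1.085
O.carbonyl.ar	carbonyl O on an aryl-substituted acyl C	0.1129	0.2215
O.carbonyl	carbonyl O	-0.1526	0.000
o.aromatic	aromatic O	0.1552	1.080
S.thio	divalent S	0.6482	7.591
P.trivalent	trivalent/pentavalent P	0.8612	6.920
F	fluorine on C	0.4202	1.108
Cl	chlorine on C	0.6895	5.853
Br	bromine on C	0.8456	8.927
I	iodine on C	0.8857	14.020
Zn.ion	zinc ion	-0.0025	0.000
H.o.acid	H on carboxylic acid O	0.2980	1.805
H.o	H on O (alcohol, phenol)	-0.2677	1.395
H.n	H on N	0.2142	0.9627
H.c	H on C	0.1230	1.057
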