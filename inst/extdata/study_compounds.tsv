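cid	name	smiles	provenance
4632	2-hydroxy-4-methoxybenzophenone	COc1ccc(C(=O)c2ccccc2)c(O)c1	from_printed_name
8569	2,2'-dihydroxy-4-methoxybenzophenone	COc1ccc(C(=O)c2ccccc2O)c(O)c1	from_printed_name
8571	bis(2,4-dihydroxyphenyl)methanone (MAXGARD 1000)	O=C(c1ccc(O)cc1O)c1ccc(O)cc1O	from_printed_name
8572	2,4-dihydroxybenzophenone	O=C(c1ccccc1)c1ccc(O)cc1O	from_printed_name
11178	zinc stearate	[Zn+2].CCCCCCCCCCCCCCCCCC(=O)[O-].CCCCCCCCCCCCCCCCCC(=O)[O-]	from_printed_name
12738	octadecyl 3-(3-octadecoxy-3-oxopropyl)sulfanylpropanoate (Songnox DSTDP)	CCCCCCCCCCCCCCCCCCOC(=O)CCSCCC(=O)OCCCCCCCCCCCCCCCCCC	from_printed_name
15797	2-hydroxy-4-n-octoxybenzophenone	CCCCCCCCOc1ccc(C(=O)c2ccccc2)c(O)c1	from_printed_name
16386	octadecyl 3-(3,5-di-tert-butyl-4-hydroxyphenyl)propanoate (Irganox 1076)	CCCCCCCCCCCCCCCCCCOC(=O)CCc1cc(C(C)(C)C)c(O)c(C(C)(C)C)c1	from_printed_name
17113	2-(2'-hydroxy-5'-methylphenyl)-benzotriazole	Cc1ccc(O)c(-n2nc3ccccc3n2)c1	from_printed_name
24667	butylated hydroxyanisole (BHA, isomer mixture; synthetic two-component record)	COc1ccc(O)c(C(C)(C)C)c1.COc1ccc(O)cc1C(C)(C)C	requires_lookup
31250	dodecyl 3-(3-dodecoxy-3-oxopropyl)sulfanylpropanoate (Irganox PS 800)	CCCCCCCCCCCCOC(=O)CCSCCC(=O)OCCCCCCCCCCCC	from_printed_name
31404	2,6-di-tert-butyl-4-methylphenol (BHT)	Cc1cc(C(C)(C)C)c(O)c(C(C)(C)C)c1	from_printed_name
62485	2-(benzotriazol-2-yl)-4-(2,4,4-trimethylpentan-2-yl)phenol (SUNSORB 5411)	CC(C)(C)CC(C)(C)c1ccc(O)c(-n2nc3ccccc3n2)c1	from_printed_name
62531	(2'-hydroxy-3'-tert-butyl-5'-methylphenyl)-5-chlorobenzotriazole	Cc1cc(C(C)(C)C)c(O)c(-n2nc3ccc(Cl)cc3n2)c1	from_printed_name
64819	pentaerythritol tetrakis(3-(3,5-di-tert-butyl-4-hydroxyphenyl)propionate) (Irganox 1010)	C(COC(=O)CCc1cc(C(C)(C)C)c(O)c(C(C)(C)C)c1)(COC(=O)CCc1cc(C(C)(C)C)c(O)c(C(C)(C)C)c1)(COC(=O)CCc1cc(C(C)(C)C)c(O)c(C(C)(C)C)c1)COC(=O)CCc1cc(C(C)(C)C)c(O)c(C(C)(C)C)c1	from_printed_name
70355	1-hydroxycyclohexyl phenyl ketone	OC1(CCCCC1)C(=O)c1ccccc1	from_printed_name
77470	2-(2'-hydroxy-3',5'-di-tert-butylphenyl)-5-chlorobenzotriazole	CC(C)(C)c1cc(C(C)(C)C)c(O)c(-n2nc3ccc(Cl)cc3n2)c1	from_printed_name
90571	2,2-dimethoxy-2-phenylacetophenone	COC(OC)(c1ccccc1)C(=O)c1ccccc1	from_printed_name
91601	tris(2,4-di-tert-butylphenyl) phosphite (ALKANOX 240)	O(c1ccc(C(C)(C)C)cc1C(C)(C)C)P(Oc1ccc(C(C)(C)C)cc1C(C)(C)C)Oc1ccc(C(C)(C)C)cc1C(C)(C)C	from_printed_name
93481	methyl 3-[3-(benzotriazol-2-yl)-5-tert-butyl-4-hydroxyphenyl]propanoate (TINUVIN 1130)	COC(=O)CCc1cc(C(C)(C)C)c(O)c(-n2nc3ccccc3n2)c1	from_printed_name
112412	2-(2H-benzotriazol-2-yl)-4,6-bis(1-methyl-1-phenylethyl)phenol	CC(C)(c1ccccc1)c1cc(C(C)(C)c2ccccc2)c(O)c(-n2nc3ccccc3n2)c1	from_printed_name
172473	butanedioic acid;1-(2-hydroxyethyl)-2,2,6,6-tetramethylpiperidin-4-ol (HALS GW 622)	OC(=O)CCC(=O)O.CC1(C)CC(O)CC(C)(C)N1CCO	from_printed_name
3601357	bis(2,6-di-tert-butyl-4-methylphenyl) pentaerythritol diphosphite (ADK STAB PEP-36)	Cc1cc(C(C)(C)C)c(OP2OCC3(CO2)COP(Oc4c(C(C)(C)C)cc(C)cc4C(C)(C)C)OC3)c(C(C)(C)C)c1	from_printed_name
4992761	2-(4,6-diphenyl-1,3,5-triazin-2-yl)-5-(hexyloxy)phenol (synthetic stand-in consistent with printed MF)	CCCCCCOc1ccc(-c2nc(-c3ccccc3)nc(-c4ccccc4)n2)c(O)c1	requires_lookup
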