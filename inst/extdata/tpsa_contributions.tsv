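key	pattern	contribution
N|0|+0|0|3|0|0|0|0	N(-*)(-*)-*	3.24
N|0|+0|0|3|0|0|0|1	N 3-ring (-*)(-*)-*	3.01
N|0|+0|0|1|1|0|0|0	N(-*)=*	12.36
N|0|+0|0|0|0|1|0|0	N#*	23.79
N|0|+0|0|1|2|0|0|0	N(-*)(=*)=*	11.68
N|0|+0|0|0|1|1|0|0	N(=*)#*	13.60
N|0|+0|1|2|0|0|0|0	N[H](-*)-*	12.03
N|0|+0|1|2|0|0|0|1	N[H] 3-ring	21.94
N|0|+0|1|0|1|0|0|0	N[H]=*	23.85
N|0|+0|2|1|0|0|0|0	N[H2]-*	26.02
N|0|+1|0|4|0|0|0|0	N+(-*)(-*)(-*)-*	0.00
N|0|+1|0|2|1|0|0|0	N+(-*)(-*)=*	3.01
N|0|+1|0|1|0|1|0|0	N+(-*)#*	4.36
N|0|+1|1|3|0|0|0|0	N+[H](-*)(-*)-*	4.44
N|0|+1|1|1|1|0|0|0	N+[H](-*)=*	13.97
N|0|+1|2|2|0|0|0|0	N+[H2](-*)-*	16.61
N|0|+1|2|0|1|0|0|0	N+[H2]=*	25.59
N|0|+1|3|1|0|0|0|0	N+[H3]-*	27.64
N|1|+0|0|0|0|0|2|0	n(:*):*	12.89
N|1|+0|0|0|0|0|3|0	n(:*)(:*):*	4.41
N|1|+0|0|1|0|0|2|0	n(-*)(:*):*	4.93
N|1|+0|0|0|1|0|2|0	n(=*)(:*):*	8.39
N|1|+0|1|0|0|0|2|0	n[H](:*):*	15.79
N|1|+1|0|0|0|0|3|0	n+(:*)(:*):*	4.10
N|1|+1|0|1|0|0|2|0	n+(-*)(:*):*	3.88
N|1|+1|1|0|0|0|2|0	n+[H](:*):*	14.14
O|0|+0|0|2|0|0|0|0	O(-*)-*	9.23
O|0|+0|0|2|0|0|0|1	O 3-ring	12.53
O|0|+0|0|0|1|0|0|0	O=*	17.07
O|0|+0|1|1|0|0|0|0	O[H]-*	20.23
O|0|-1|0|1|0|0|0|0	O-(-*)	23.06
O|1|+0|0|0|0|0|2|0	o(:*):*	13.14
S|0|+0|0|2|0|0|0|0	S(-*)-*	25.30
S|0|+0|0|0|1|0|0|0	S=*	32.09
S|0|+0|0|2|1|0|0|0	S(-*)(-*)=*	19.21
S|0|+0|0|2|2|0|0|0	S(-*)(-*)(=*)=*	8.38
S|0|+0|1|1|0|0|0|0	S[H]-*	38.80
S|1|+0|0|0|0|0|2|0	s(:*):*	28.24
S|1|+0|0|0|1|0|2|0	s(=*)(:*):*	21.70
P|0|+0|0|3|0|0|0|0	P(-*)(-*)-*	13.59
P|0|+0|0|1|1|0|0|0	P(-*)=*	34.14
P|0|+0|0|3|1|0|0|0	P(-*)(-*)(-*)=*	9.81
P|0|+0|1|2|1|0|0|0	P[H](-*)(-*)=*	23.47
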