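codon	amino_acid	count	rscu_published
UUU	F	369	1.9
UUC	F	20	0.1
UUA	L	478	5.32
UUG	L	14	0.16
CUU	L	24	0.27
CUC	L	3	0.03
CUA	L	19	0.21
CUG	L	1	0.01
AUU	I	452	1.9
AUC	I	25	0.1
AUA	M	285	1.89
AUG	M	17	0.11
GUU	V	66	2.08
GUC	V	1	0.03
GUA	V	56	1.76
GUG	V	4	0.13
UCU	S	94	2.39
UCC	S	10	0.25
UCA	S	97	2.47
UCG	S	0	0
CCU	P	60	1.98
CCC	P	10	0.33
CCA	P	48	1.59
CCG	P	3	0.1
ACU	T	67	1.91
ACC	T	6	0.17
ACA	T	67	1.91
ACG	T	0	0
GCU	A	65	2.39
GCC	A	3	0.11
GCA	A	39	1.43
GCG	A	2	0.07
UAU	Y	178	1.87
UAC	Y	12	0.13
UAA	*	11	2
UAG	*	0	0
CAU	H	57	1.73
CAC	H	9	0.27
CAA	Q	60	2
CAG	Q	0	0
AAU	N	246	1.82
AAC	N	24	0.18
AAA	K	107	1.88
AAG	K	7	0.12
GAU	D	62	1.88
GAC	D	4	0.12
GAA	E	66	1.83
GAG	E	6	0.17
UGU	C	29	1.81
UGC	C	3	0.19
UGA	W	90	1.94
UGG	W	3	0.06
CGU	R	14	1.06
CGC	R	0	0
CGA	R	38	2.87
CGG	R	1	0.08
AGU	S	30	0.76
AGC	S	1	0.03
AGA	S	82	2.09
AGG	S	0	0
GGU	G	52	1.09
GGC	G	1	0.02
GGA	G	126	2.65
GGG	G	11	0.23
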