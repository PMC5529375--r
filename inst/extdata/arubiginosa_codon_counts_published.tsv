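codon	amino_acid	count	rscu_published
UUU	F	347	1.88
UUC	F	23	0.12
UUA	L	482	5.32
UUG	L	14	0.15
CUU	L	26	0.29
CUC	L	2	0.02
CUA	L	20	0.22
CUG	L	0	0
AUU	I	452	1.91
AUC	I	22	0.09
AUA	M	276	1.86
AUG	M	21	0.14
GUU	V	74	2.26
GUC	V	1	0.03
GUA	V	55	1.68
GUG	V	1	0.03
UCU	S	91	2.35
UCC	S	1	0.03
UCA	S	103	2.66
UCG	S	0	0
CCU	P	63	1.98
CCC	P	12	0.38
CCA	P	52	1.64
CCG	P	0	0
ACU	T	83	2.26
ACC	T	6	0.16
ACA	T	56	1.52
ACG	T	2	0.05
GCU	A	75	2.59
GCC	A	0	0
GCA	A	40	1.38
GCG	A	1	0.03
UAU	Y	184	1.86
UAC	Y	14	0.14
UAA	*	10	2
UAG	*	0	0
CAU	H	57	1.73
CAC	H	9	0.27
CAA	Q	63	2
CAG	Q	0	0
AAU	N	239	1.85
AAC	N	19	0.15
AAA	K	102	1.92
AAG	K	4	0.08
GAU	D	58	1.9
GAC	D	3	0.1
GAA	E	70	1.87
GAG	E	5	0.13
UGU	C	31	1.82
UGC	C	3	0.18
UGA	W	91	1.94
UGG	W	3	0.06
CGU	R	13	1
CGC	R	0	0
CGA	R	37	2.85
CGG	R	2	0.15
AGU	S	22	0.57
AGC	S	0	0
AGA	S	92	2.37
AGG	S	1	0.03
GGU	G	62	1.29
GGC	G	0	0
GGA	G	111	2.31
GGG	G	19	0.4
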