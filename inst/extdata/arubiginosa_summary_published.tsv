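gene	klass	strand	start	end	anticodon	start_codon	stop_codon	size	intergenic
trnM	tRNA	F	1	68	CAT	NA	NA	68	0
trnI	tRNA	F	69	132	GAT	NA	NA	64	-3
trnQ	tRNA	R	130	198	TTG	NA	NA	69	56
nad2	PCG	F	255	1266	NA	ATT	T	1012	0
trnW	tRNA	F	1267	1334	TCA	NA	NA	68	-8
trnC	tRNA	R	1327	1391	GCA	NA	NA	65	0
trnY	tRNA	R	1392	1456	GTA	NA	NA	65	6
cox1	PCG	F	1463	2990	NA	CGA	T	1528	0
trnL2	tRNA	F	2991	3058	TAA	NA	NA	68	0
cox2	PCG	F	3059	3740	NA	ATG	T	682	0
trnK	tRNA	F	3741	3811	CTT	NA	NA	71	2
trnD	tRNA	F	3814	3881	GTC	NA	NA	68	0
atp8	PCG	F	3882	4043	NA	ATT	TAA	162	-7
atp6	PCG	F	4037	4714	NA	ATG	TAA	678	0
cox3	PCG	F	4715	5506	NA	ATG	TAA	792	2
trnG	tRNA	F	5509	5574	TCC	NA	NA	66	0
nad3	PCG	F	5575	5926	NA	ATT	T	352	0
trnA	tRNA	F	5927	5993	TGC	NA	NA	67	1
trnR	tRNA	F	5995	6058	TCG	NA	NA	64	0
trnN	tRNA	F	6059	6124	GTT	NA	NA	66	0
trnS1	tRNA	F	6125	6186	GCT	NA	NA	62	9
trnE	tRNA	F	6196	6263	TTC	NA	NA	68	-2
trnF	tRNA	R	6262	6327	GAA	NA	NA	66	27
nad5	PCG	R	6355	8076	NA	ATT	A	1722	15
trnH	tRNA	R	8092	8155	GTG	NA	NA	64	0
nad4	PCG	R	8156	9490	NA	ATG	TAA	1335	0
nad4L	PCG	R	9491	9781	NA	ATG	TAA	291	4
trnT	tRNA	F	9786	9851	TGT	NA	NA	66	-1
trnP	tRNA	R	9851	9916	TGG	NA	NA	66	6
nad6	PCG	F	9923	10453	NA	ATG	TAA	531	6
cob	PCG	F	10460	11608	NA	ATG	TAA	1149	-1
trnS2	tRNA	F	11608	11672	TGA	NA	NA	65	21
nad1	PCG	R	11694	12629	NA	ATG	TAA	936	0
trnL1	tRNA	R	12630	12696	TAG	NA	NA	67	0
rrnL	rRNA	R	12697	14040	NA	NA	NA	1344	0
trnV	tRNA	R	14041	14108	TAC	NA	NA	68	0
rrnS	rRNA	R	14109	14883	NA	NA	NA	775	0
AT_rich_region	control	F	14884	15282	NA	NA	NA	399	NA
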