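gene	klass	strand	start	end	anticodon	start_codon	stop_codon	size	intergenic
trnM	tRNA	F	1	68	CAT	NA	NA	68	0
trnI	tRNA	F	69	132	GAT	NA	NA	64	-3
trnQ	tRNA	R	130	198	TTG	NA	NA	69	52
nad2	PCG	F	251	1264	NA	ATT	TAA	1014	7
trnW	tRNA	F	1272	1338	TCA	NA	NA	67	-8
trnC	tRNA	R	1331	1394	GCA	NA	NA	64	0
trnY	tRNA	R	1395	1459	GTA	NA	NA	65	9
cox1	PCG	F	1469	2999	NA	CGA	T	1531	0
trnL2	tRNA	F	3000	3066	TAA	NA	NA	67	0
cox2	PCG	F	3067	3748	NA	ATG	T	682	0
trnK	tRNA	F	3749	3819	CTT	NA	NA	71	-1
trnD	tRNA	F	3819	3884	GTC	NA	NA	66	0
atp8	PCG	F	3885	4046	NA	ATC	TAA	162	-7
atp6	PCG	F	4040	4717	NA	ATG	TAA	678	3
cox3	PCG	F	4721	5509	NA	ATG	TAA	789	2
trnG	tRNA	F	5512	5577	TCC	NA	NA	66	0
nad3	PCG	F	5575	5931	NA	ATA	TAA	357	27
trnA	tRNA	F	5959	6032	TGC	NA	NA	74	10
trnR	tRNA	F	6043	6105	TCG	NA	NA	63	0
trnN	tRNA	F	6106	6173	GTT	NA	NA	68	6
trnS1	tRNA	F	6180	6248	GCT	NA	NA	69	1
trnE	tRNA	F	6250	6314	TTC	NA	NA	65	3
trnF	tRNA	R	6318	6385	GAA	NA	NA	68	0
nad5	PCG	R	6386	8124	NA	ATT	TA	1739	0
trnH	tRNA	R	8125	8190	GTG	NA	NA	66	10
nad4	PCG	R	8201	9541	NA	ATG	TAA	1341	5
nad4L	PCG	R	9547	9837	NA	ATG	TAA	291	2
trnT	tRNA	F	9840	9904	TGT	NA	NA	65	0
trnP	tRNA	R	9905	9970	TGG	NA	NA	66	2
nad6	PCG	F	9973	10503	NA	ATG	TAA	531	7
cob	PCG	F	10511	11665	NA	ATG	TAA	1155	10
trnS2	tRNA	F	11676	11727	TGA	NA	NA	52	33
nad1	PCG	R	11761	12699	NA	ATG	TAA	939	1
trnL1	tRNA	R	12701	12770	TAG	NA	NA	70	0
rrnL	rRNA	R	12771	14186	NA	NA	NA	1416	0
trnV	tRNA	R	14187	14252	TAC	NA	NA	66	0
rrnS	rRNA	R	14253	15032	NA	NA	NA	780	0
AT_rich_region	control	F	15033	15636	NA	NA	NA	604	NA
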