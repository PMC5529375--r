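region	size	A	T	G	C	pctA	pctT	pctG	pctC	pctAT	at_skew	gc_skew
whole_genome	15282	6334	6126	1144	1678	41.4	40.1	7.5	11.0	81.5	0.017	-0.189
PCGs	11175	3894	5090	1135	1056	34.8	45.5	10.2	9.5	80.3	-0.133	0.038
tRNAs	1461	602	589	116	154	41.2	40.3	7.9	10.6	81.5	0.011	-0.141
rRNAs	2119	906	887	104	222	42.8	41.9	4.9	10.4	84.7	0.011	-0.362
AT_rich_region	399	174	194	14	17	43.6	48.6	3.5	4.3	92.2	-0.054	-0.097
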