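region	size	A	T	G	C	pctA	pctT	pctG	pctC	pctAT	at_skew	gc_skew
whole_genome	15636	6561	6290	1122	1663	42.0	40.2	7.2	10.6	82.2	0.021	-0.194
PCGs	11205	3934	5107	1114	1050	35.1	45.6	9.9	9.4	80.7	-0.130	0.030
tRNAs	1460	606	588	115	151	41.5	40.3	7.9	10.3	81.8	0.015	-0.135
rRNAs	2196	959	927	100	210	43.7	42.2	4.5	9.6	85.9	0.017	-0.355
AT_rich_region	604	281	287	18	18	46.5	47.5	3.0	3.0	94.0	-0.011	0
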