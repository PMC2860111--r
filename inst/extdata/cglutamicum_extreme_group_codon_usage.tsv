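# Pooled codon usage of putatively highly (n_high) and lowly (n_low)
# expressed genes of Corynebacterium glutamicum ATCC 13032, i.e. the two
# extremes of the first codon-usage ordination axis. rscu_high/rscu_low are
# the published 2-d.p. RSCU values; starred = 1 marks codons reported as
# significantly (P < .01) more used in the highly expressed group.
aa	codon	n_high	rscu_high	n_low	rscu_low	starred
Phe	UUU	149	0.17	1058	1.37	0
Phe	UUC	1608	1.83	481	0.63	1
Leu	UUA	19	0.03	486	0.78	0
Leu	UUG	239	0.33	1284	2.06	0
Leu	CUU	656	0.91	707	1.13	0
Leu	CUC	1583	2.21	341	0.55	1
Leu	CUA	140	0.2	274	0.44	0
Leu	CUG	1666	2.32	651	1.04	1
Ile	AUU	412	0.43	1207	1.71	0
Ile	AUC	2477	2.57	654	0.93	1
Ile	AUA	7	0.01	257	0.36	0
Met	AUG	1143	1	863	1	0
Val	GUU	1495	1.45	883	1.11	1
Val	GUC	1631	1.59	452	0.57	1
Val	GUA	336	0.33	396	0.5	0
Val	GUG	650	0.63	1443	1.82	0
Tyr	UAU	47	0.07	632	1.41	0
Tyr	UAC	1311	1.93	262	0.59	1
TER	UAA	100	2.19	39	0.85	0
TER	UAG	33	0.72	51	1.12	0
His	CAU	47	0.09	560	1.35	0
His	CAC	981	1.91	271	0.65	1
Gln	CAA	284	0.34	539	0.79	0
Gln	CAG	1385	1.66	830	1.21	1
Asn	AAU	141	0.13	795	1.37	0
Asn	AAC	1955	1.87	369	0.63	1
Lys	AAA	298	0.26	664	0.91	0
Lys	AAG	2014	1.74	800	1.09	1
Asp	GAU	959	0.55	1537	1.53	0
Asp	GAC	2559	1.45	468	0.47	1
Glu	GAA	2117	1.04	1095	0.91	1
Glu	GAG	1941	0.96	1313	1.09	0
Ser	UCU	371	0.77	539	1.22	0
Ser	UCC	1972	4.11	284	0.64	1
Ser	UCA	175	0.36	360	0.82	0
Ser	UCG	59	0.12	676	1.53	0
Pro	CCU	527	0.92	492	1.11	0
Pro	CCC	185	0.32	205	0.46	0
Pro	CCA	1454	2.55	371	0.84	1
Pro	CCG	119	0.21	705	1.59	0
Thr	ACU	304	0.38	605	1.2	0
Thr	ACC	2758	3.45	427	0.85	1
Thr	ACA	74	0.09	378	0.75	0
Thr	ACG	61	0.08	601	1.2	0
Ala	GCU	1707	1.18	957	1.08	1
Ala	GCC	1138	0.79	512	0.58	1
Ala	GCA	2529	1.75	789	0.89	1
Ala	GCG	411	0.28	1300	1.46	0
Cys	UGU	64	0.44	213	1.3	0
Cys	UGC	230	1.56	114	0.7	1
TER	UGA	4	0.09	47	1.03	0
Trp	UGG	577	1	661	1	0
Arg	CGU	744	1.62	557	1.45	0
Arg	CGC	1887	4.11	362	0.94	1
Arg	CGA	89	0.19	317	0.83	0
Arg	CGG	16	0.03	489	1.27	0
Ser	AGU	19	0.04	483	1.09	0
Ser	AGC	284	0.59	305	0.69	0
Arg	AGA	5	0.01	236	0.62	0
Arg	AGG	13	0.03	341	0.89	0
Gly	GGU	1026	0.93	1069	1.46	0
Gly	GGC	2830	2.55	562	0.77	1
Gly	GGA	549	0.5	568	0.78	0
Gly	GGG	26	0.02	724	0.99	0
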