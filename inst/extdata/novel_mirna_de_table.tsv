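mirna_id	log2fc	direction	adj_p	sequence
novel_mir_70	15.60	up	0	UCGGGCGGGAGUGGUGGCUUU
novel_mir_48	7.87	up	1.05E-08	AGGGGCGCGGCCCAGGAGCUCA
novel_mir_71	7.22	up	8.78E-06	UGGGCAGGGGCUUAUUGUAGGAG
novel_mir_62	7.00	up	4.72E-05	UGCCCGGCGGUGUGCGGCCACA
novel_mir_63	6.92	up	8.27E-05	CUCCUGCGUAGGAUCUGAGGAGU
novel_mir_54	6.83	up	1.45E-04	GGCGGGGCGUGUGCGGCUGCUG
novel_mir_60	6.73	up	2.54E-04	UUGAGGGGAGAAUGAGGUGGAGA
novel_mir_43	4.32	up	1.47E-130	CGGUGGCGGCGGCGGCGGCGGGA
novel_mir_36	-16.30	down	0	UCGGGCGGGAGUGGUGGCUUUU
novel_mir_31	-7.63	down	1.66E-08	AUGGGGAGGUGUGGAGUCAGCAU
novel_mir_18	-7.41	down	2.10E-07	UGAGGGGAGAAUGAGGUGGAGA
novel_mir_14	-7.05	down	6.18E-06	UCCUGGAGCUGGGCAGAUGGGA
novel_mir_38	-7.05	down	6.18E-06	UGGGCAGGGGCUUAUUGUAGGAGU
novel_mir_3	-6.94	down	1.44E-05	UCAGGGAGAAAGAAGGGUUAUU
novel_mir_4	-6.70	down	7.82E-05	AGGGGCGCGGCCCAGGAGCUC
novel_mir_30	-1.41	down	2.01E-02	UCGGGCGGGAGUGGUGGCUUUU
novel_mir_25	-1.32	down	3.27E-02	AUGGGGAGGUGUGGAGUCAGCAU
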