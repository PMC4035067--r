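transcript_id	annotation	fpkm_ctrl_a	fpkm_salt_a	fpkm_ctrl_b	fpkm_salt_b	log2_a	log2_b
POPTR_0008s17940.1	glyceraldehyde-3-phosphate dehydrogenase	17.64	430.78	19.83	321.82	4.61	4.02
POPTR_0006s25280.1	malate dehydrogenase (NADP+)	48.70	190.54	28.89	85.17	1.97	1.56
POPTR_0007s14250.1	phosphoenolpyruvate carboxykinase [ATP]	82.37	565.15	92.96	253.92	2.78	1.45
POPTR_0006s11590.1	ABC transporter G family member 39	3.02	36.26	5.99	17.88	3.59	1.58
POPTR_0001s26210.1	catalytic/cation binding/hydrolase	0.05	132.37	0.00	15.30	11.41	13.90
POPTR_0015s05290.1	alpha/beta-hydrolase domain-containing protein	1.90	17.84	0.63	10.20	3.23	4.02
POPTR_0016s01570.1	UDP-glycosyltransferase-like protein	2.87	20.08	2.06	13.49	2.81	2.71
POPTR_0006s12220.1	UDP-glucosyl transferase 73D1	1.27	20.29	1.56	18.09	4.00	3.54
POPTR_0005s21690.1	ethylene-responsive transcription factor ERF112	0.93	27.49	1.18	23.49	4.89	4.32
POPTR_0002s04020.1	ethylene-responsive transcription factor 1B	1.44	28.29	3.29	14.91	4.29	2.18
POPTR_0008s14670.1	potassium transporter 6	35.29	191.46	55.07	133.58	2.44	1.28
POPTR_0010s09370.1	homocysteine S-methyltransferase 3	0.13	16.64	0.31	12.10	7.04	5.28
POPTR_0015s11130.1	putative WRKY transcription factor 75	24.38	143.60	30.56	286.38	2.56	3.23
POPTR_0010s10010.1	sugar transport protein 13	5.48	116.42	8.20	72.52	4.41	3.15
POPTR_0001s09000.1	osmotin-like protein OSM34	0.07	245.80	1.04	165.57	11.83	7.32
POPTR_0004s22170.1	glycosyltransferase family protein 2	0.09	4.58	0.19	3.96	5.68	4.40
POPTR_0009s15100.1	arogenate dehydratase 6	37.86	158.76	31.10	154.12	2.07	2.31
POPTR_0017s04590.1	tyrosine aminotransferase	29.34	253.35	24.46	201.65	3.11	3.04
POPTR_0006s16610.1	phosphorylase-like protein	6.75	153.46	4.72	113.79	4.51	4.59
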