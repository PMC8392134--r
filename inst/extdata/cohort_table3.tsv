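patient_id	panel	phenotype	gene	hgvs	clinical_class
1	EP1.0V	malignant PGL	SDHB	SDHB(NM_003000.3):c.728G>A	pathogenic
2	EP1.0V	Pheo	NA	NA	NA
3	EP1.0V	malignant PGL	SDHB	SDHB(NM_003000.3):c.586T>G	pathogenic
4	EP1.0V	malignant PGL	NA	NA	NA
5	EP1.0V	Pheo	NA	NA	NA
6	EP1.0V	MEN2	RET	RET(NM_020975.6):c.1832G>A	pathogenic
7	EP1.0V	Pheo	TMEM127	TMEM127(NM_001193304.3):c.419G>A	likely_pathogenic
8	EP1.0V	Pheo	NA	NA	NA
9	EP1.0V	malignant PGL	SDHB	SDHB(NM_003000.3):c.745T>C	likely_pathogenic
10	EP1.0V	malignant PGL	SDHB	SDHB(NM_003000.3):c.649C>T	likely_pathogenic
11	EP1.0V	malignant PGL	SDHB	SDHB(NM_003000.3):c.758G>A	pathogenic
12	EP1.0V	MEN2B	RET	RET(NM_020975.6):c.2753T>C	pathogenic
13	EP1.0V	Pheo	TMEM127	TMEM127(NM_001193304.3):c.320delG	likely_pathogenic
14	EP1.0V	VHL	VHL	VHL(NM_000551.4):c.407T>G	likely_pathogenic
15	EP1.0V	Pheo	NA	NA	NA
16	EP1.0P	Pheo	NA	NA	NA
17	EP1.0P	Pheo	NA	NA	NA
18	EP1.0P	Pheo	NA	NA	NA
19	EP1.0P	malignant PGL	SDHB	SDHB(NM_003000.3):c.286+2T>A	likely_pathogenic
20	EP1.0P	PGL	NA	NA	NA
21	EP1.0P	NF1	NF1	NF1(NM_001042492.3):c.1756_1759delACTA	pathogenic
22	EP1.0P	NF1	NF1	NF1(NM_001042492.2):c.5047_5053delinsGGAG	vus
23	EP1.0P	NF1	NF1	NF1(NM_001042492.2):c.4230_4231delCC	likely_pathogenic
24	EP1.0P	NF1	NF1	NF1(NM_001042492.2):c.1466A>G	pathogenic
25	EP1.0P	NF1	NF1	NF1(NM_001042492.2):c.2251+1G>A	likely_pathogenic
26	EP1.0P	NF1	NF1	NF1(NM_001042492.2):c.7465_7466insG	likely_pathogenic
27	EP1.0P	Pheo	NA	NA	NA
28	EP1.0P	NF1	NF1	NF1(NM_001042492.2):c.4175dupT	likely_pathogenic
29	EP1.0P	Pheo	NA	NA	NA
30	EP1.0P	Pheo	NA	NA	NA
31	EP1.0P	Pheo	NA	NA	NA
32	EP1.0P	Pheo	NA	NA	NA
33	EP1.0P	Pheo	NA	NA	NA
34	EP1.0P	PGL-glomus caroticum	VHL	VHL(NM_000551.4):c.123_137dupAGAGTCCGGCCCGGA	vus
35	EP1.0P	Pheo	NA	NA	NA
36	EP1.0P	malignant PGL	SDHB	SDHB(NM_003000.3):c.263C>T	vus
36	EP1.0P	malignant PGL	SDHB	SDHB(NM_003000.3):c.268C>G	vus
36	EP1.0P	malignant PGL	SDHB	SDHB(NM_003000.3):c.271_273del	likely_pathogenic
37	EP1.0P	Pheo	NA	NA	NA
38	EP1.0P	Pheo	NA	NA	NA
39	EP1.0P	Pheo	NA	NA	NA
40	EP2.0	Pheo	NA	NA	NA
41	EP2.0	Pheo	SDHB	SDHB(NM_003000.3):c.193C>T	likely_pathogenic
42	EP2.0	Pheo	NA	NA	NA
43	EP2.0	Pheo	NA	NA	NA
44	EP2.0	Pheo	NA	NA	NA
45	EP2.0	Pheo	NA	NA	NA
46	EP2.0	Pheo	NA	NA	NA
47	EP2.0	Pheo	NA	NA	NA
48	EP2.0	Pheo	VHL	VHL(NM_000551.4):c.576delA	likely_pathogenic
49	EP2.0	Pheo	NA	NA	NA
50	EP2.0	Pheo&PGL	SDHB	SDHB(NM_003000.3):c.286+2T>A	likely_pathogenic
51	EP2.0	Pheo	FH	FH(NM_000143.4):c.1127A>C	likely_pathogenic
52	EP2.0	Pheo	NA	NA	NA
53	EP2.0	Pheo	NA	NA	NA
54	EP2.0	abdominal PGL	SDHB	SDHB(NM_003000.3):c.689G>A	pathogenic
55	EP2.0	Pheo	NA	NA	NA
56	EP2.0	Pheo	NA	NA	NA
57	EP2.0	malignant PGL	NA	NA	NA
58	EP2.0	Pheo	NA	NA	NA
59	EP2.0	Pheo	NA	NA	NA
60	EP2.0	cervical PGL	NA	NA	NA
61	EP2.0	NF1	NF1	NF1(NM_001042492.2):c.3456dupA	pathogenic
62	EP2.0	Pheo	NA	NA	NA
63	EP2.0	NF1	NF1	NF1(NM_001042492.2):c.888+2T>G	pathogenic
64	EP2.0	Pheo	NA	NA	NA
65	EP2.0	Fumarase deficient leiomyoma	FH	FH(NM_000143.4):c.1256C>T	likely_pathogenic
66	EP2.0	Pheo	NA	NA	NA
67	EP2.0	Pheo	MDH2	MDH2(NM_005918.4):c.686G>A	vus
68	EP2.0	Pheo	SDHA	SDHA(NM_004168.4):c.837G>T	vus
69	EP2.0	Pheo	NA	NA	NA
70	EP2.0	Pheo	NA	NA	NA
71	EP2.0	Pheo	RET	RET(NM_020975.6):c.2372A>T	vus
72	EP2.0	NF1	NF1	NF1(NM_001042492.2):c.6850_6853delACTT	pathogenic
72	EP2.0	NF1	SDHC	SDHC(NM_003001.5):c.94A>G	vus
73	EP2.0	Pheo	NA	NA	NA
74	EP2.0	Pheo	NA	NA	NA
75	EP2.0	Pheo	NA	NA	NA
76	EP2.0	NF1	NF1	NF1(NM_001042492.3):c.2991-1G>C	pathogenic
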