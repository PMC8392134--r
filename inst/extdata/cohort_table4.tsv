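sample_id	manifestations	age	tumor_behavior	gene	hgvs	clinical_class
22	Neurofibromatosis type 1: multiple neurofibromas; adrenal pheochromocytoma	30	benign	NF1	NF1(NM_001042492.2):c.5047_5053delinsGGAG	vus
23	Neurofibromatosis type 1: multiple neurofibromas	32	benign	NF1	NF1(NM_001042492.2):c.4230_4231delCC	likely_pathogenic
26	Neurofibromatosis type 1: adrenal pheochromocytoma	15	benign	NF1	NF1(NM_001042492.2):c.7465_7466insG	likely_pathogenic
28	Neurofibromatosis type 1	26	benign	NF1	NF1(NM_001042492.2):c.4175dupT	likely_pathogenic
36	Extra-adrenal PGL	14	malignant	SDHB	SDHB(NM_003000.3):c.263C>T	vus
36	Extra-adrenal PGL	14	malignant	SDHB	SDHB(NM_003000.3):c.268C>G	vus
36	Extra-adrenal PGL	14	malignant	SDHB	SDHB(NM_003000.3):c.271_273del	likely_pathogenic
48	Adrenal pheochromocytoma	15	benign	VHL	VHL(NM_000551.4):c.576delA	likely_pathogenic
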