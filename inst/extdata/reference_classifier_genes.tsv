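model	gene
classifier_1	ASS1
classifier_1	BAP1
classifier_1	CAV1
classifier_1	CCNB1
classifier_1	CD44
classifier_1	CDH1
classifier_1	EGR3
classifier_1	FN1
classifier_1	ITGA3
classifier_1	KRT5
classifier_1	LAMA3
classifier_1	LGALS3
classifier_1	MICAL2
classifier_1	MMP9
classifier_1	MYH11
classifier_1	NME2
classifier_1	NMU
classifier_1	PAPPA
classifier_1	PECAM1
classifier_1	PKM
classifier_1	RAD21
classifier_1	TGFBR2
classifier_2	ASS1
classifier_2	BAP1
classifier_2	CAV1
classifier_2	CCNB1
classifier_2	CD44
classifier_2	CDH1
classifier_2	CDH11
classifier_2	COL4A2
classifier_2	CTNNA1
classifier_2	CXADR
classifier_2	EEF2
classifier_2	EGR3
classifier_2	EIF4G1
classifier_2	FANCI
classifier_2	FN1
classifier_2	GALNT7
classifier_2	GLI2
classifier_2	HEG1
classifier_2	IFITM1
classifier_2	ITGA3
classifier_2	KRT5
classifier_2	LAMA3
classifier_2	LGALS3
classifier_2	MAGED1
classifier_2	MICAL2
classifier_2	MMP9
classifier_2	MYH11
classifier_2	NME2
classifier_2	NMU
classifier_2	PAK4
classifier_2	PAPPA
classifier_2	PECAM1
classifier_2	PKM
classifier_2	PTGS2
classifier_2	RAD21
classifier_2	SDC1
classifier_2	SMARCA4
classifier_2	TGFBR2
classifier_2	TOP2A
classifier_2	VEGFA
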