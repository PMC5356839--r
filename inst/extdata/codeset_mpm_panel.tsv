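CodeClass	Name	Accession
Endogenous	ACSL1	CUST_ACSL1
Endogenous	ADAMTS8	CUST_ADAMTS8
Endogenous	ADCY4	CUST_ADCY4
Endogenous	ASS1	CUST_ASS1
Endogenous	AURKA	CUST_AURKA
Endogenous	BAP1	CUST_BAP1
Endogenous	BIRC5	CUST_BIRC5
Endogenous	BMP1	CUST_BMP1
Endogenous	BUB1	CUST_BUB1
Endogenous	CAV1	CUST_CAV1
Endogenous	CCNB1	CUST_CCNB1
Endogenous	CCNB2	CUST_CCNB2
Endogenous	CCNO	CUST_CCNO
Endogenous	CD274	CUST_CD274
Endogenous	CD44	CUST_CD44
Endogenous	CDH1	CUST_CDH1
Endogenous	CDH11	CUST_CDH11
Endogenous	CDK1	CUST_CDK1
Endogenous	CDK4	CUST_CDK4
Endogenous	CDK7	CUST_CDK7
Endogenous	CDKN2A	CUST_CDKN2A
Endogenous	CDKN2B	CUST_CDKN2B
Endogenous	CENPF	CUST_CENPF
Endogenous	CFB	CUST_CFB
Endogenous	CHEK1	CUST_CHEK1
Endogenous	CLDN15	CUST_CLDN15
Endogenous	COL16A1	CUST_COL16A1
Endogenous	COL1A1	CUST_COL1A1
Endogenous	COL4A2	CUST_COL4A2
Endogenous	CTNNA1	CUST_CTNNA1
Endogenous	CXADR	CUST_CXADR
Endogenous	DNMT1	CUST_DNMT1
Endogenous	DNMT3A	CUST_DNMT3A
Endogenous	DSP	CUST_DSP
Endogenous	EEF2	CUST_EEF2
Endogenous	EGFR	CUST_EGFR
Endogenous	EGR3	CUST_EGR3
Endogenous	EIF4G1	CUST_EIF4G1
Endogenous	EMX2	CUST_EMX2
Endogenous	ESR2	CUST_ESR2
Endogenous	FANCI	CUST_FANCI
Endogenous	FGF2	CUST_FGF2
Endogenous	FN1	CUST_FN1
Endogenous	GALNT7	CUST_GALNT7
Endogenous	GLI1	CUST_GLI1
Endogenous	GLI2	CUST_GLI2
Endogenous	GNAQ	CUST_GNAQ
Endogenous	HEG1	CUST_HEG1
Endogenous	IFITM1	CUST_IFITM1
Endogenous	ITGA3	CUST_ITGA3
Endogenous	ITGA4	CUST_ITGA4
Endogenous	ITGA5	CUST_ITGA5
Endogenous	ITGA7	CUST_ITGA7
Endogenous	ITGAM	CUST_ITGAM
Endogenous	ITGB4	CUST_ITGB4
Endogenous	JAG1	CUST_JAG1
Endogenous	JUNB	CUST_JUNB
Endogenous	KRT5	CUST_KRT5
Endogenous	LAMA3	CUST_LAMA3
Endogenous	LAMC1	CUST_LAMC1
Endogenous	LGALS3	CUST_LGALS3
Endogenous	LGALS3BP	CUST_LGALS3BP
Endogenous	MAD2L1	CUST_MAD2L1
Endogenous	MAGED1	CUST_MAGED1
Endogenous	MCM2	CUST_MCM2
Endogenous	MCM4	CUST_MCM4
Endogenous	MICAL2	CUST_MICAL2
Endogenous	MKI67	CUST_MKI67
Endogenous	MMP1	CUST_MMP1
Endogenous	MMP10	CUST_MMP10
Endogenous	MMP12	CUST_MMP12
Endogenous	MMP14	CUST_MMP14
Endogenous	MMP3	CUST_MMP3
Endogenous	MMP7	CUST_MMP7
Endogenous	MMP9	CUST_MMP9
Endogenous	MSLN	CUST_MSLN
Endogenous	MYH11	CUST_MYH11
Endogenous	NDC80	CUST_NDC80
Endogenous	NF2	CUST_NF2
Endogenous	NME2	CUST_NME2
Endogenous	NMU	CUST_NMU
Endogenous	NOTCH1	CUST_NOTCH1
Endogenous	PAK4	CUST_PAK4
Endogenous	PAPPA	CUST_PAPPA
Endogenous	PCNA	CUST_PCNA
Endogenous	PDCD1	CUST_PDCD1
Endogenous	PDGFRB	CUST_PDGFRB
Endogenous	PECAM1	CUST_PECAM1
Endogenous	PIK3CA	CUST_PIK3CA
Endogenous	PKM	CUST_PKM
Endogenous	PLK1	CUST_PLK1
Endogenous	PLK2	CUST_PLK2
Endogenous	PPARA	CUST_PPARA
Endogenous	PTGIS	CUST_PTGIS
Endogenous	PTGS2	CUST_PTGS2
Endogenous	RAD21	CUST_RAD21
Endogenous	SDC1	CUST_SDC1
Endogenous	SDHB	CUST_SDHB
Endogenous	SELE	CUST_SELE
Endogenous	SERPINE1	CUST_SERPINE1
Endogenous	SFRP1	CUST_SFRP1
Endogenous	SMARCA4	CUST_SMARCA4
Endogenous	SOD1	CUST_SOD1
Endogenous	SULF1	CUST_SULF1
Endogenous	TACC1	CUST_TACC1
Endogenous	TERT	CUST_TERT
Endogenous	TGFBR2	CUST_TGFBR2
Endogenous	THBS2	CUST_THBS2
Endogenous	TIMP3	CUST_TIMP3
Endogenous	TNPO2	CUST_TNPO2
Endogenous	TOP2A	CUST_TOP2A
Endogenous	TPPP	CUST_TPPP
Endogenous	TUBB2B	CUST_TUBB2B
Endogenous	UBE2T	CUST_UBE2T
Endogenous	VEGFA	CUST_VEGFA
Endogenous	VWF	CUST_VWF
Endogenous	XPOT	CUST_XPOT
Housekeeping	CLTC	REF_CLTC
Housekeeping	GAPDH	REF_GAPDH
Housekeeping	GUSB	REF_GUSB
Housekeeping	HPRT1	REF_HPRT1
Housekeeping	PGK1	REF_PGK1
Housekeeping	TUBB	REF_TUBB
Positive	POS_A(128)	ERCC_POS_A
Positive	POS_B(32)	ERCC_POS_B
Positive	POS_C(8)	ERCC_POS_C
Positive	POS_D(2)	ERCC_POS_D
Positive	POS_E(0.5)	ERCC_POS_E
Positive	POS_F(0.125)	ERCC_POS_F
Negative	NEG_A(0)	ERCC_NEG_A
Negative	NEG_B(0)	ERCC_NEG_B
Negative	NEG_C(0)	ERCC_NEG_C
Negative	NEG_D(0)	ERCC_NEG_D
Negative	NEG_E(0)	ERCC_NEG_E
Negative	NEG_F(0)	ERCC_NEG_F
Negative	NEG_G(0)	ERCC_NEG_G
Negative	NEG_H(0)	ERCC_NEG_H
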