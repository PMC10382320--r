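FOXM1_PPARA_UP	up tags	AURKB	BIRC5	BRCA2	CCNA2	CCNB1	CCNB2	CCNE1	CDC25B	CDK1	CDK2	CDK4	CDKN2A	CENPA	CENPF	CHEK2	CKS1B	FOXM1	GSK3A	NEK2	PLK1	SKP2
FOXM1_PPARA_DN	down tags	STAT5B	HSD17B4	PIK3R1	DUSP1	CD36	CITED2	STAT5A	SP1	PRKAR1A	NCOA1	JUN	MAPK3	LPL	PRKAR2B	NCOR1	RB1	RXRA	NR2F1	EHHADH	ACOX1	PRKACB	NRIP1	PDGFA	NR1H3	CREBBP	PRKAR2A
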