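FOXM1_UP	up tags	AURKB	BIRC5	BRCA2	CCNA2	CCNB1	CCNB2	CCND1	CCNE1	CDC25B	CDK1	CDK2	CDK4	CDKN2A	CENPA	CENPB	CENPF	CHEK2	CKS1B	ESR1	FOXM1	GSK3A	HIST1H2BA	NEK2	ONECUT1	PLK1	SKP2	XRCC1
FOXM1_DN	down tags	CREBBP	EP300	ETV5	FOS	GAS1	LAMA4	MAP2K1	MMP2	MYC	NFATC3	RB1	SP1	TGFA
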