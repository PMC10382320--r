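PPARA_UP	up tags	APOA1	APOA2	DUT	HSP90AA1	HSPA1A	INS	MED1	MRPL11	NCOR2	NR0B2	RELA	SRA1
PPARA_DN	down tags	ACOX1	CD36	CITED2	CPT1B	CREBBP	DUSP1	EHHADH	EP300	FABP1	FAT1	HSD17B4	JUN	LPL	MAPK1	MAPK3	ME1	MYC	NCOA1	NCOR1	NFKBIA	NOS2	NR1H3	NR2F1	NRIP1	PDGFA	PIK3CA	PIK3CG	PIK3R1	PPARA	PPARGC1A	PRKACB	PRKACG	PRKAR1A	PRKAR1B	PRKAR2A	PRKAR2B	PRKCA	PRKCB	PTGS2	RB1	RXRA	SP1	STAT5A	STAT5B	TNF
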