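gene	direction	is_core
APOA1	up	FALSE
APOA2	up	FALSE
DUT	up	FALSE
HSP90AA1	up	FALSE
HSPA1A	up	FALSE
INS	up	FALSE
MED1	up	FALSE
MRPL11	up	FALSE
NCOR2	up	FALSE
NR0B2	up	FALSE
RELA	up	FALSE
SRA1	up	FALSE
ACOX1	down	TRUE
CD36	down	TRUE
CITED2	down	TRUE
CPT1B	down	FALSE
CREBBP	down	TRUE
DUSP1	down	TRUE
EHHADH	down	TRUE
EP300	down	FALSE
FABP1	down	FALSE
FAT1	down	FALSE
HSD17B4	down	TRUE
JUN	down	TRUE
LPL	down	TRUE
MAPK1	down	FALSE
MAPK3	down	TRUE
ME1	down	FALSE
MYC	down	FALSE
NCOA1	down	TRUE
NCOR1	down	TRUE
NFKBIA	down	FALSE
NOS2	down	FALSE
NR1H3	down	TRUE
NR2F1	down	TRUE
NRIP1	down	TRUE
PDGFA	down	TRUE
PIK3CA	down	FALSE
PIK3CG	down	FALSE
PIK3R1	down	TRUE
PPARA	down	FALSE
PPARGC1A	down	FALSE
PRKACB	down	TRUE
PRKACG	down	FALSE
PRKAR1A	down	TRUE
PRKAR1B	down	FALSE
PRKAR2A	down	TRUE
PRKAR2B	down	TRUE
PRKCA	down	FALSE
PRKCB	down	FALSE
PTGS2	down	FALSE
RB1	down	TRUE
RXRA	down	TRUE
SP1	down	TRUE
STAT5A	down	TRUE
STAT5B	down	TRUE
TNF	down	FALSE
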