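gene	direction	is_core
AURKB	up	TRUE
BIRC5	up	TRUE
BRCA2	up	TRUE
CCNA2	up	TRUE
CCNB1	up	TRUE
CCNB2	up	TRUE
CCND1	up	FALSE
CCNE1	up	TRUE
CDC25B	up	TRUE
CDK1	up	TRUE
CDK2	up	TRUE
CDK4	up	TRUE
CDKN2A	up	TRUE
CENPA	up	TRUE
CENPB	up	FALSE
CENPF	up	TRUE
CHEK2	up	TRUE
CKS1B	up	TRUE
ESR1	up	FALSE
FOXM1	up	TRUE
GSK3A	up	TRUE
HIST1H2BA	up	FALSE
NEK2	up	TRUE
ONECUT1	up	FALSE
PLK1	up	TRUE
SKP2	up	TRUE
XRCC1	up	FALSE
CREBBP	down	FALSE
EP300	down	FALSE
ETV5	down	FALSE
FOS	down	FALSE
GAS1	down	FALSE
LAMA4	down	FALSE
MAP2K1	down	FALSE
MMP2	down	FALSE
MYC	down	FALSE
NFATC3	down	FALSE
RB1	down	FALSE
SP1	down	FALSE
TGFA	down	FALSE
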