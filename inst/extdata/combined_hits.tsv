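rank	drug	dose_uM	n	up_score	down_score	connectivity
1	MG-262	0.1	1	-0.55	0.19	-0.91
2	clotrimazole	50	1	-0.32	0.34	-0.82
3	MG-132	21	1	-0.52	0.14	-0.81
4	hycanthone	11	2	-0.44	0.15	-0.73
5	celastrol	3	1	-0.43	0.15	-0.72
6	ciclopirox	15	2	-0.46	0.11	-0.71
7	withaferin A	1	2	-0.39	0.18	-0.7
8	cephaeline	6	3	-0.35	0.19	-0.67
9	pararosaniline	10	1	-0.31	0.23	-0.67
10	puromycin	7	2	-0.34	0.19	-0.66
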