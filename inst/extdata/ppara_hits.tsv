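drug	dose_uM	n	rank_activity	rank_connectivity	as_t	as_c	as_d	connectivity
anisomycin	15	2	1	15	2.71	-0.26	2.96	-0.66
cephaeline	6	3	2	48	3.01	0.61	2.4	-0.58
pararosaniline	10	1	3	4	2.52	0.3	2.22	-0.73
cycloheximide	14.2	2	6	39	2.05	-0.02	2.08	-0.61
monensin	10.9	1	17	21	0.34	-1.23	1.57	-0.64
wortmannin	1	2	18	44	2.75	1.18	1.56	-0.6
raloxifene	0.1	1	24	47	0.72	-0.66	1.38	-0.58
prednisolone	1	1	25	8	0.65	-0.73	1.38	-0.71
valinomycin	0.1	2	34	29	1.11	-0.09	1.2	-0.62
oligomycin	1	1	37	31	0.51	-0.63	1.15	-0.62
mepacrine	7.8	1	44	14	0.93	-0.1	1.03	-0.66
5186324	2	1	47	20	1.31	0.3	1.01	-0.65
5162773	7	1	48	30	1.31	0.3	1.01	-0.62
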