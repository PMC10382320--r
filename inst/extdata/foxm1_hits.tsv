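drug	dose_uM	n	rank_activity	rank_connectivity	as_t	as_c	as_d	connectivity
5109870	25	1	1	10	-8.57	1.59	-10.16	-0.66
MG-132	21	1	2	1	-4.45	1.97	-6.42	-1
MG-262	0.1	1	4	3	-2.95	1.79	-4.74	-0.83
celastrol	2.5	1	5	7	-2.99	1.59	-4.58	-0.72
resveratrol	50	2	6	8	0.92	5.2	-4.28	-0.7
ciclopirox	15	2	7	37	-2.45	1.53	-3.98	-0.59
pyrvinium	3.4	2	11	2	-1.85	1.56	-3.41	-0.84
emetine	7.2	2	13	14	-1.37	1.71	-3.08	-0.63
15-delta prostaglandin J2	10	8	14	11	-1.18	1.73	-2.91	-0.66
cephaeline	6	3	15	32	-0.95	1.96	-2.91	-0.6
puromycin	7.4	2	16	17	-0.94	1.89	-2.84	-0.62
parthenolide	16.2	2	23	18	-1.43	1.03	-2.46	-0.62
azacitidine	16.4	2	24	49	-0.87	1.53	-2.39	-0.57
cycloheximide	14.2	2	28	45	-0.3	2	-2.29	-0.57
astemizole	8.8	2	29	27	0.04	2.3	-2.26	-0.65
224221	1	2	36	25	-1.42	0.61	-2.03	-0.6
scriptaid	10	1	42	20	1.32	3.29	-1.97	-0.62
ouabain	5.4	2	43	30	-0.34	1.63	-1.97	-0.6
bepridil	10	2	49	13	0.12	2	-1.88	-0.63
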