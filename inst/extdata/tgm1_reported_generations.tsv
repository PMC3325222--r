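mutation	marker	estimator	founder_allele	distance_mb	generations
c.2278C>T	D14S1043	bergman	5	3.34	40
c.2278C>T	D14S72	bergman	3	3.32	65
c.2278C>T	D14S742	bergman	6	2.52	29
c.2278C>T	D14S275	bergman	8	1.98	20
c.2278C>T	D14S1042	bergman	1	4.54	19
c.2278C>T	D14S1060	bergman	9	8.7	NA
c.2278C>T	D14S1043	risch	5	3.34	NA
c.2278C>T	D14S72	risch	3	3.32	33
c.2278C>T	D14S742	risch	6	2.52	29
c.2278C>T	D14S275	risch	8	1.98	20
c.2278C>T	D14S1042	risch	1	4.54	13
c.2278C>T	D14S1060	risch	9	8.7	7
c.2278C>T	D14S1043	labuda	5	3.34	NA
c.2278C>T	D14S72	labuda	3	3.32	52
c.2278C>T	D14S742	labuda	6	2.52	37
c.2278C>T	D14S275	labuda	8	1.98	31
c.2278C>T	D14S1042	labuda	1	4.54	21
c.2278C>T	D14S1060	labuda	9	8.7	11
c.1223_1227delACACA	D14S1043	bergman	3	NA	NA
c.1223_1227delACACA	D14S72	bergman	5	3.33	18
c.1223_1227delACACA	D14S742	bergman	5	2.53	24
c.1223_1227delACACA	D14S275	bergman	6	1.97	23
c.1223_1227delACACA	D14S1042	bergman	3	4.53	20
c.1223_1227delACACA	D14S1060	bergman	10	8.69	10
c.1223_1227delACACA	D14S1043	risch	3	NA	NA
c.1223_1227delACACA	D14S72	risch	5	3.33	26
c.1223_1227delACACA	D14S742	risch	5	2.53	24
c.1223_1227delACACA	D14S275	risch	6	1.97	23
c.1223_1227delACACA	D14S1042	risch	3	4.53	20
c.1223_1227delACACA	D14S1060	risch	10	8.69	NA
c.1223_1227delACACA	D14S1043	labuda	3	NA	NA
c.1223_1227delACACA	D14S72	labuda	5	3.33	45
c.1223_1227delACACA	D14S742	labuda	5	2.53	34
c.1223_1227delACACA	D14S275	labuda	6	1.97	35
c.1223_1227delACACA	D14S1042	labuda	3	4.53	29
c.1223_1227delACACA	D14S1060	labuda	10	8.69	NA
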