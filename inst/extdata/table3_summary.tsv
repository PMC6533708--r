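genome_id	chromosome_length_mbp	cds_count	trna	rrna	hypothetical_pct	assigned_pct	is_elements	prophage	crispr	gc_pct	plasmid_count	plasmid_min_kb	plasmid_max_kb	spoiler
100D8	2.35	2228	66	15	21.2	78.8	25	1 In 3 Pa	NA	46.1	3	39.9	45.1	FALSE
ATCC367	2.29	2133	65	15	20.8	79.2	34	1 In	NA	46.2	2	13.4	35.6	FALSE
BDGP6	2.79	2674	71	15	23.1	76.9	24	4 In 3 Pa	1	46.6	0	NA	NA	FALSE
KB290	2.40	2308	64	15	21.4	78.6	50	2 In 2 Pa	NA	46.1	9	5.9	42.4	FALSE
NCTC13768	2.49	2413	65	15	15.0	85.0	3	1 Pa	NA	46.0	0	NA	NA	FALSE
NPS-QW-145	2.55	2406	62	13	21.5	78.5	5	3 Pa	1	45.8	0	NA	NA	FALSE
SA-C12	2.44	2344	66	15	23.2	76.7	42	2 In 3 Pa	NA	45.9	2	24.8	43.6	FALSE
SRCM101106	2.44	2379	67	15	23.0	77.0	46	3 In 4 Pa	1	45.9	4	16.0	36.2	FALSE
SRCM101174	2.41	2353	68	15	24.0	76.0	37	3 In 2 Pa	NA	46.1	5	9.4	50.4	FALSE
TMW1.2108	2.57	2448	66	15	22.8	77.2	17	2 In	NA	45.8	8	5.1	107.0	TRUE
TMW1.2111	2.57	2458	66	15	21.8	78.2	22	2 In	NA	45.8	6	8.2	107.0	TRUE
TMW1.2112	2.49	2283	65	15	19.6	80.4	29	1 In 1 Pa	1	46.0	5	8.5	59.7	TRUE
TMW1.2113	2.54	2376	69	15	22.5	77.5	30	2 In	1	45.9	4	8.5	46.6	TRUE
UCCLB521	2.27	2088	62	15	20.0	80.0	32	2 Pa	NA	46.3	5	11.3	43.8	FALSE
UCCLB556	2.38	2201	66	18	22.8	77.2	32	1 Pa	NA	46.1	7	4.3	68.4	FALSE
UCCLB95	2.51	2283	65	15	22.7	77.3	132	1 In 1 Pa	NA	45.9	2	3.5	14.0	TRUE
UCCLBBS124	2.61	2442	66	15	21.8	78.2	60	1 In 2 Pa	NA	45.8	4	21.0	49.6	TRUE
UCCLBBS449	2.58	2404	66	15	21.1	78.9	114	1 In 3 Pa	NA	45.8	9	2.8	66.8	TRUE
ZLB004	2.66	2207	64	15	24.0	76.0	29	1 In	2	46.0	5	16.7	78.1	FALSE
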