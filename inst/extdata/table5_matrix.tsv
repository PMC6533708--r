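family_id	product	category	TMW1.2108	TMW1.2111	TMW1.2112	TMW1.2113	UCCLB95	UCCLBBS124	UCCLBBS449
t5_01	Flavodoxin	Energy production and conversion	1	1	1	1	1	1	1
t5_02	NADH-Flavin reductase	Energy production and conversion	1	1	0	0	1	1	1
t5_03	Oxidoreductase	Energy production and conversion	1	1	1	1	1	1	1
t5_04	NADPH:quinone reductase	Energy production and conversion	1	1	0	0	1	1	1
t5_05	FMN-dependent NADH-azoreductase	Energy production and conversion	1	1	0	0	1	1	1
t5_06	Nitrobenzoate reductase	Energy production and conversion	1	1	0	0	1	1	1
t5_07	Shikimate dehydrogenase	Amino acid transport and metabolism	1	1	1	1	1	1	1
t5_08	Acetyltransferase GNAT family	Amino acid transport and metabolism	1	1	0	0	1	1	1
t5_09	Serine O-acetyltransferase EC	Amino acid transport and metabolism	1	1	0	0	1	1	1
t5_10	MFS transporter	Carbohydrate transport and metabolism	1	1	0	0	1	1	1
t5_11	Alpha-glucosidase	Carbohydrate transport and metabolism	1	1	1	1	1	1	1
t5_12	lycoside hydrolase	Carbohydrate transport and metabolism	1	1	0	0	0	1	1
t5_13	Hydrolase	Carbohydrate transport and metabolism	1	1	1	1	1	1	1
t5_14	Transketolase	Carbohydrate transport and metabolism	1	1	1	1	0	0	0
t5_15	MFS transporter	Carbohydrate transport and metabolism	1	1	1	0	1	1	0
t5_16	PTS system2C IIA component 1	Carbohydrate transport and metabolism	1	1	0	0	1	1	1
t5_17	Putative integral membrane protein 1	Carbohydrate transport and metabolism	1	1	0	0	1	1	1
t5_18	PTS2C EIIB 1	Carbohydrate transport and metabolism	1	1	0	0	1	1	1
t5_19	PTS mannitol transporter subunit IIA	Carbohydrate transport and metabolism	1	1	0	0	1	1	1
t5_20	Putative oligogalacturonide transporter	Carbohydrate transport and metabolism	1	1	1	1	1	0	1
t5_21	6-pyruvoyl tetrahydropterin synthase	Coenzyme transport and metabolism	1	1	1	1	0	1	0
t5_22	NADH peroxidase	Lipid transport and metabolism	1	1	1	1	1	1	1
t5_23	Peroxidase	Lipid transport and metabolism	1	1	0	0	1	1	1
t5_24	Citrate lyase	Lipid transport and metabolism	1	1	0	0	1	1	1
t5_25	Transcriptional regulator2C TetR family	Transcription	1	1	0	0	1	1	1
t5_26	Transcriptional regulator	Transcription	1	1	1	1	1	1	1
t5_27	Transcriptional regulator TetR family	Transcription	1	1	0	0	1	1	1
t5_28	Transcriptional regulator	Transcription	1	1	1	1	1	1	1
t5_29	Internalin-J	Transcription	0	1	1	1	1	1	1
t5_30	RNA polymerase sigma-24 subunit ECF subfamily	Transcription	1	1	1	1	1	1	1
t5_31	ECF-type sigma factor negative effector	Transcription	1	1	1	1	1	1	1
t5_32	Transcriptional regulator	Transcription	1	1	1	1	1	1	1
t5_33	Transcriptional regulator MarR family	Transcription	1	1	0	0	1	1	1
t5_34	Transcriptional regulator	Transcription	1	1	0	0	1	1	1
t5_35	Transcriptional regulator MarR family	Transcription	1	1	0	0	1	1	1
t5_36	Transcriptional regulator TetR	Transcription	1	1	0	0	0	1	1
t5_37	Transcriptional regulator ArsR family	Transcription	1	1	0	0	1	1	1
t5_38	Membrane protein	Cell wall/membrane/envelope biogenesis	1	1	0	1	0	1	0
t5_39	Cell surface protein	Cell wall/membrane/envelope biogenesis	1	1	1	1	0	0	0
t5_40	Cell surface protein	Cell wall/membrane/envelope biogenesis	1	1	0	0	0	1	1
t5_41	Endo polygalacturonase	Cell wall/membrane/envelope biogenesis	1	1	1	1	0	0	1
t5_42	Glutamyl endopeptidase precursor	Cell wall/membrane/envelope biogenesis	1	1	1	1	1	1	1
t5_43	NLP-P60 protein	Cell wall/membrane/envelope biogenesis	1	1	1	1	1	1	1
t5_44	Short-chain dehydrogenase-oxidoreductase	Cell wall/membrane/envelope biogenesis	1	1	0	0	1	1	1
t5_45	Permease	Inorganic ion transport and metabolism	1	1	1	1	1	1	1
t5_46	Permease	Inorganic ion transport and metabolism	1	1	1	1	1	0	1
t5_47	Na + -H+ antiporter	Inorganic ion transport and metabolism	1	1	0	0	1	1	0
t5_48	NADPH-quinone reductase	General function prediction only	1	1	1	1	1	1	1
t5_49	Short-chain dehydrogenase-oxidoreductase	General function prediction only	1	1	1	1	1	1	1
t5_50	Short-chain dehydrogenase	General function prediction only	1	1	1	1	1	1	0
t5_51	Cell surface adherence protein	General function prediction only	0	0	1	1	1	1	1
t5_52	Mucus-binding protein LPXTG-motif cell wall anchor	General function prediction only	1	1	1	1	1	0	1
t5_53	Cell surface hydrolase	Function unknown	1	1	1	1	1	1	1
t5_54	Membrane protein	Function unknown	1	1	1	1	0	1	1
t5_55	Cell surface protein	Function unknown	1	1	0	0	1	1	1
t5_56	ABC transporter ATP-binding protein	Defence mechanisms	1	1	1	1	1	1	1
t5_57	ABC transporter permease	Defence mechanisms	1	1	1	1	1	1	1
t5_58	Prophage protein	Defence mechanisms	1	1	1	1	0	0	1
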