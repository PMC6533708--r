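family_id	product	category	TMW1.2108	TMW1.2111	TMW1.2112	TMW1.2113	UCCLB95	UCCLBBS124	UCCLBBS449
t6_01	Membrane protein HorC	Defence mechanisms	1	1	1	0	1	1	1
t6_02	Lipopolysaccharide biosynthesis glycosyltransferase	Cell wall biogenesis	1	1	1	1	0	1	1
t6_03	Lipopolysaccharide biosynthesis glycosyltransferase	Cell wall biogenesis	1	1	1	1	0	1	1
t6_04	Phospholipid-glycerol acyltransferase	Lipid transport and metabolism	1	1	1	1	0	1	1
t6_05	1-acyl-sn-glycerol-3-phosphate acyltransferase	Lipid transport and metabolism	1	1	1	1	0	1	1
t6_06	Fatty acid-binding protein DegV	Lipid transport and metabolism	0	0	1	1	0	1	1
t6_07	Glycosyl transferase family 2	Carbohydrate transport and metabolism	1	1	1	0	0	1	0
t6_08	Enolase	Carbohydrate transport and metabolism	1	1	0	0	0	0	1
t6_09	MFS transporter	Carbohydrate transport and metabolism	1	1	1	1	0	0	0
t6_10	Sigma-70 region 4 family protein	Transcription	1	1	0	0	0	0	1
t6_11	Transcriptional regulator TetR family	Transcription	1	1	1	0	0	1	1
t6_12	Cytosine deaminase	Nucleotide transport and metabolism	1	1	0	1	0	1	1
t6_13	CrcB-like protein	Inorganic ion transport and metabolism	1	1	0	0	0	0	1
t6_14	Cytosine-specific methyltransferase	Replication, recombination and repair	1	1	0	0	0	1	0
t6_15	Initiator RepB protein	Replication, recombination and repair	1	1	0	0	0	0	1
t6_16	Hypothetical protein	Function unknown	1	1	0	0	0	0	1
t6_17	Hypothetical protein	Function unknown	1	1	1	1	0	0	1
t6_18	Hypothetical protein	Function unknown	1	1	1	1	0	0	0
t6_19	Hypothetical protein	Function unknown	1	1	0	0	0	0	1
t6_20	Hypothetical protein	Function unknown	1	1	0	0	0	1	0
t6_21	Hypothetical protein	Function unknown	1	0	1	0	0	1	0
t6_22	PemK family protein	Function unknown	1	1	0	0	0	1	0
t6_23	Transposase	Mobilome	1	1	0	0	0	1	0
t6_24	Mobilization protein	Mobilome	1	1	0	0	0	0	1
t6_25	Mobilization protein	Mobilome	1	1	0	0	0	0	1
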