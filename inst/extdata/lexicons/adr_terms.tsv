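llt_code	llt_name	pt_code	pt_name	soc_name	synonyms	is_ime
L001	huiduitslag	P001	huiduitslag	Skin and subcutaneous tissue disorders	exantheem	0
L002	jeuk	P002	jeuk	Skin and subcutaneous tissue disorders	pruritus	0
L003	urticaria	P003	urticaria	Skin and subcutaneous tissue disorders		0
L004	erytheem	P004	erytheem	Skin and subcutaneous tissue disorders		0
L005	misselijkheid	P005	misselijkheid	Gastrointestinal disorders	nausea	0
L006	braken	P006	braken	Gastrointestinal disorders		0
L007	diarree	P007	diarree	Gastrointestinal disorders		0
L008	obstipatie	P008	obstipatie	Gastrointestinal disorders		0
L009	buikpijn	P009	buikpijn	Gastrointestinal disorders		0
L010	duizeligheid	P010	duizeligheid	Nervous system disorders	vertigo	0
L011	hoofdpijn	P011	hoofdpijn	Nervous system disorders	cefalgie	0
L012	tremor	P012	tremor	Nervous system disorders		0
L013	convulsie	P013	convulsie	Nervous system disorders	insult	1
L014	sufheid	P014	sufheid	Nervous system disorders		0
L015	verwardheid	P015	verwardheid	Psychiatric disorders	delier	0
L016	slapeloosheid	P016	slapeloosheid	Psychiatric disorders	insomnia	0
L017	bradycardie	P017	bradycardie	Cardiac disorders		0
L018	tachycardie	P018	tachycardie	Cardiac disorders		0
L019	hypotensie	P019	hypotensie	Vascular disorders		0
L020	hartfalen	P020	hartfalen	Cardiac disorders	decompensatio	1
L021	nierfalen	P021	nierfalen	Renal and urinary disorders	nierinsufficientie	1
L022	hematurie	P022	hematurie	Renal and urinary disorders		0
L023	urineretentie	P023	urineretentie	Renal and urinary disorders		0
L024	anemie	P024	anemie	Blood and lymphatic system disorders	bloedarmoede	0
L025	trombocytopenie	P025	trombocytopenie	Blood and lymphatic system disorders		1
L026	neutropenie	P026	neutropenie	Blood and lymphatic system disorders		1
L027	agranulocytose	P027	agranulocytose	Blood and lymphatic system disorders		1
L028	anafylaxie	P028	anafylaxie	Immune system disorders		1
L029	leverfalen	P029	leverfalen	Hepatobiliary disorders		1
L030	icterus	P030	icterus	Hepatobiliary disorders	geelzucht	0
L031	dyspnoe	P031	dyspnoe	Respiratory, thoracic and mediastinal disorders	kortademigheid	0
L032	koorts	P032	koorts	General disorders and administration site conditions	pyrexie	0
L033	oedeem	P033	oedeem	General disorders and administration site conditions	vochtretentie	0
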