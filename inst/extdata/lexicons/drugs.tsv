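drug_id	generic_name	brand_names	abbreviations	class_names
D01	amoxicilline	clamoxyl	amox	antibiotica
D02	trimetoprim	monotrim		antibiotica
D03	ciprofloxacine	ciproxin		antibiotica
D04	metoprolol	selokeen		betablokker
D05	bisoprolol			betablokker
D06	simvastatine	zocor		statine
D07	atorvastatine	lipitor		statine
D08	ibuprofen	brufen		nsaid
D09	naproxen	aleve		nsaid
D10	omeprazol	losec		protonpompremmer
D11	pantoprazol			protonpompremmer
D12	metformine		mtf	antidiabeticum
D13	gliclazide			antidiabeticum
D14	furosemide	lasix		diureticum
D15	bumetanide			diureticum
D16	enalapril	renitec		aceremmer
D17	lisinopril			aceremmer
D18	amlodipine	norvasc		calciumantagonist
D19	apixaban	eliquis		anticoagulans
D20	rivaroxaban	xarelto		anticoagulans
D21	prednison			corticosteroid
D22	morfine			opiaat
D23	oxycodon	oxynorm		opiaat
D24	paracetamol	panadol	pcm	analgeticum
D25	citalopram	cipramil		ssri
D26	sertraline	zoloft		ssri
D27	haloperidol	haldol		antipsychoticum
D28	digoxine	lanoxin		cardiacum
D29	levothyroxine	euthyrox	ltx	schildklierhormoon
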