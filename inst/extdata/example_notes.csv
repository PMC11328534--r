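patient_id,note_id,form_name,category,author_role,timestamp,text
p001,n00001,Opname,consult,aios,2018-01-02T08:00:00Z,"patient komt vandaag op controle

verder geen nieuwe klachten vandaag"
p001,n00002,Ontslagbrief,consult,arts,2018-01-03T08:00:00Z,"anamnese:
eet en drinkt voldoende. controle over twee weken afgesproken

lichamelijk onderzoek zonder bijzonderheden

controle over twee weken afgesproken. verder geen nieuwe klachten vandaag

beleid besproken met familie. ontslag naar huis gepland"
p001,n00003,Dagstatus,labuitslag,verpleegkundige,2018-01-04T08:00:00Z,"mobiliseert rustig op de afdeling. beleid besproken met familie

patient komt vandaag op controle. verder geen nieuwe klachten vandaag

laboratorium uitslagen worden vervolgd. bloeddruk en pols stabiel"
p001,n00004,Consult 2.0,consult,verpleegkundige,2018-01-05T08:00:00Z,"conclusie:
afspraak gemaakt voor telefonisch consult

controle over twee weken afgesproken

mobiliseert rustig op de afdeling. gezien op de polikliniek"
p002,n00005,Dagstatus,consult,apotheker,2018-01-06T08:00:00Z,"allergie vertigo gisteren gisteren gisteren gisteren toen ibuprofen

bloeddruk en pols stabiel. gezien op de polikliniek

beleid besproken met familie. bloeddruk en pols stabiel

gezien op de polikliniek"
p002,n00006,Consult 2.0,anamnese,apotheker,2018-01-07T08:00:00Z,"anamnese:
lichamelijk onderzoek zonder bijzonderheden

bijwerking verwardheid gisteren gisteren gisteren onlangs ibuprofen

mobiliseert rustig op de afdeling. lichamelijk onderzoek zonder bijzonderheden

bloeddruk en pols stabiel. gezien op de polikliniek

mobiliseert rustig op de afdeling. patient komt vandaag op controle"
p002,n00007,Dagstatus,consult,apotheker,2018-01-08T08:00:00Z,"patient komt vandaag op controle. ontslag naar huis gepland

lichamelijk onderzoek zonder bijzonderheden

laboratorium uitslagen worden vervolgd. ontslag naar huis gepland"
p002,n00008,Ontslagbrief,anamnese,aios,2018-01-09T08:00:00Z,"lichamelijk onderzoek zonder bijzonderheden

allergie koorts gisteren gisteren gisteren dan amoxicilline

eet en drinkt voldoende

verder geen nieuwe klachten vandaag. laboratorium uitslagen worden vervolgd"
p003,n00009,Opname,anamnese,verpleegkundige,2018-01-10T08:00:00Z,"lichamelijk onderzoek zonder bijzonderheden

patient komt vandaag op controle. bloeddruk en pols stabiel

gezien op de polikliniek

gezien op de polikliniek"
p003,n00010,Dagstatus,beleid,arts,2018-01-11T08:00:00Z,"controle over twee weken afgesproken. gezien op de polikliniek

eet en drinkt voldoende. verder geen nieuwe klachten vandaag

patient komt vandaag op controle

mobiliseert rustig op de afdeling. afspraak gemaakt voor telefonisch consult"
p003,n00011,Consult 2.0,consult,arts,2018-01-12T08:00:00Z,"gezien op de polikliniek. afspraak gemaakt voor telefonisch consult

laboratorium uitslagen worden vervolgd

ontslag naar huis gepland. bloeddruk en pols stabiel"
p003,n00012,Consult 2.0,beleid,apotheker,2018-01-13T08:00:00Z,"afspraak gemaakt voor telefonisch consult. verder geen nieuwe klachten vandaag

lichamelijk onderzoek zonder bijzonderheden

bloeddruk en pols stabiel

laboratorium uitslagen worden vervolgd. controle over twee weken afgesproken"
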