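lineage	AMM	UA
Pseudomonadaceae	15,24	12,98
Alcanivoracaceae	4,99	3,94
Halomonadaceae	5,20	7,80
Enterobacteriaceae	5,62	3,15
Vibrionaceae	4,01	2,26
Aeromonadaceae	0,90	3,11
Alteromonadaceae	9,57	19,18
Chromatiaceae	1,06	0,85
Idiomarinaceae	0,36	0,81
Legionellaceae	0,23	0,91
Methylococcaceae	0,54	1,05
Moraxellaceae	0,45	7,89
Oceanospirillaceae	4,26	4,15
Pseudoalteromonadaceae	0,40	2,18
Shewanellaceae	2,78	2,59
Rhodobacteraceae	18,20	0,81
Comamonadaceae	1,64	0,54
Flavobacteriaceae	1,75	5,69
Actinobacteria	1,81	2,56
Firmicutes	4,86	7,42
Others	16,12	10,29
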