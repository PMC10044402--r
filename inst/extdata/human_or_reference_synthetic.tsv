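gene	accession	odorants	or_class
OR1A1	Q9P1Q5	(S)-(-)-citronellol;(S)-(-)-citronellal;(+)-carvone	II
OR1A2	Q9Y585	(S)-(-)-citronellal;(+)-carvone	II
OR1D2	P34982	Bourgeonal	II
OR1E3	Q8WZA6	Acetophenone	II
OR1G1	P47890	Nonanal;1-nonanol;2-ethyl-1-hexanol;gamma-decalactone;Ethyl isobutyrate;Isoamyl acetate	II
OR2A25	A4D2G3	Geranyl acetate	II
OR2AG1	Q9H205	Amylbutyrate	II
OR2B11	Q5JQS5	Coumarin	II
OR2C1	O95371	Nonanethiol;Octanethiol	II
OR2J2	O76002	1-heptanol;1-octanol;1-nonanol;1-decanol;Coumarin;Ethyl vanilin;cis-3-hexen-1-ol	II
OR2J3	O76001	cis-3-hexen-1-ol;Geranyl acetate;Cinnamaldehyde	II
OR2M7	Q8NG81	Geraniol;(-)-beta-citronellol	II
OR2W1	Q9Y3N9	allyl phenyl acetate;cis-3-hexen-1-ol;Citral;citronellal	II
OR3A1	P47881	Helional;Lilial	II
OR4D6	Q8NGJ1	beta-ionone	II
OR4D9	Q8NGE8	beta-ionone	II
OR4Q3	Q8NH05	Eugenol	II
OR5A1	Q8NGJ0	beta-ionone	II
OR5A2	Q8NGI9	beta-ionone	II
OR5AN1	Q8NGI8	Muscone	II
OR5D18	Q8NGL1	Eugenol;isoeugenol	II
OR5K1	Q8NHB7	Eugenol methyl ether	II
OR5P3	Q8WZ94	1-hexanol;1-heptanol;(-)-carvone;(+)-carvone;Acetophenone;Coumarin;1-octanol;celery ketone	II
OR6P1	Q8NGX9	Anisaldehyde	II
OR7C1	O76099	Androstadienone	II
OR7D4	Q8NG98	Androsterone;Androstadienone	II
OR8B3	Q8NGG8	(+)-carvone	II
OR8D1	Q8WZ84	Caramel furanone	II
OR8K3	Q8NH51	(+)-menthol	II
OR10A6	Q8NH74	3-phenyl propyl propionate	II
OR10G3	Q8NGC4	Ethyl vanillin;Vanillin	II
OR10G4	Q8NGN3	Guaiacol;Vanillin	II
OR10G7	Q8NGN6	Eugenol	II
OR10G9	Q8NGN4	Ethyl vanillin	II
OR10J5	Q8NHC4	Lyral	II
OR11A1	Q9GZK7	2-ethyl fenchol	II
OR11H4	Q8NGC9	Isovaleric acid	II
OR11H6	Q8NGC7	Isovaleric acid	II
OR11H7P	Q8NGC8	Isovaleric acid	II
OR51E1	Q8TCB6	Nonanoic acid;Butyl butyryllactate;Butyric acid;Isovaleric acid;Propionic acid	I
OR51E2	Q9H255	Propionic acid	I
OR51L1	Q8NGJ5	Hexanoic acid;Allyl phenyl acetate	I
OR52D1	Q9H346	Ethyl heptanoate;Methyl octanoate;1-nonanol;2-nonanol;3-nonanone;3-octanone	I
OR56A1	Q8NGH5	Undecanal	I
OR56A4	Q8NGH8	Decyl adehyde;Undecanal	I
OR56A5	P0C7T3	Undecanal	I
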