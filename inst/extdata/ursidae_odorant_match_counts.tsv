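gene	AIL	AME	ARC	MAR	THI	TRE
OR1A1	1	1	0	0	1	1
OR1A2	0	1	0	1	0	0
OR1D2	2	1	1	1	2	0
OR1E3	1	1	1	1	0	2
OR1G1	1	1	0	0	1	1
OR2A25	1	0	0	0	4	0
OR2AG1	0	1	1	1	0	0
OR2B11	0	2	2	2	4	2
OR2C1	2	0	2	2	2	3
OR2J2	0	1	0	1	0	0
OR2J3	0	1	0	1	0	0
OR2M7	2	5	1	3	2	1
OR2W1	1	0	0	3	1	1
OR3A1	0	11	0	1	0	0
OR4D6	1	1	0	0	1	0
OR4D9	1	0	3	2	0	0
OR4Q3	0	2	0	2	0	0
OR5A1	0	0	0	1	1	0
OR5A2	0	0	0	1	1	0
OR5AN1	5	1	2	0	1	0
OR5D18	1	0	1	0	1	0
OR5K1	4	8	5	8	2	2
OR5P3	1	1	1	1	1	1
OR6P1	1	1	1	1	1	1
OR7C1	3	9	5	5	19	1
OR7D4	1	1	0	1	1	1
OR8B3	1	0	1	1	2	0
OR8D1	1	2	3	1	3	0
OR8K3	1	0	1	0	0	1
OR10A6	1	2	3	1	3	0
OR10G3	0	4	2	2	2	1
OR10G4	1	1	1	0	0	0
OR10G7	1	1	1	0	0	0
OR10G9	1	1	1	0	0	0
OR10J5	1	2	2	2	2	2
OR11A1	0	0	0	0	1	1
OR11H4	5	7	3	5	4	2
OR11H6	0	5	1	5	2	2
OR11H7P	0	5	1	5	2	2
OR51E1	0	0	0	1	0	0
OR51E2	0	0	0	1	0	0
OR51L1	4	1	1	0	0	1
OR52D1	2	1	0	1	4	0
OR56A1	1	2	0	2	1	0
OR56A4	1	2	0	2	1	0
OR56A5	1	2	0	2	1	0
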