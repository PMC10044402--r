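chrom_id	size_mb	functional	partial	pseudogene	subfamilies
Chr1	212.77	12	2	2	10
Chr2	199.81	6	0	3	5
Chr3	147.63	9	0	4	9
Chr4	147.79	15	0	3	14
Chr5	130.99	6	1	3	6
Chr6	131.59	4	0	0	4
Chr7	141.53	13	0	2	11
Chr8	129.35	36	1	7	36
Chr9	103.69	0	0	0	0
Chr10	110.58	4	0	0	3
Chr11	110.51	0	0	0	0
Chr12	81.78	4	0	0	2
Chr13	92.46	6	0	0	4
Chr14	106.65	0	1	0	0
Chr15	91.61	4	0	1	4
Chr16	91.34	30	1	7	25
Chr17	42.25	6	0	2	6
Chr18	38.12	3	0	1	3
Chr19	35.68	0	0	0	0
Chr20	30.94	5	0	5	5
ChrX	112.85	7	1	5	7
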