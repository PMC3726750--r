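group	species	genome_size_mb	assembled_size_mb	printed_pct	n_units
chromosome	Arabidopsis thaliana	125	119	95.2	5
chromosome	Brachypodium distachyon	272	271	99.63	5
chromosome	Fragaria vesca	240	195	81.25	7
chromosome	Glycine max	1100	950	86.36	20
chromosome	Lotus japonicus	472	463	98.09	6
chromosome	Malus x domestica	742	526	70.89	17
chromosome	Medicago truncatula	308	291	94.48	8
chromosome	Oryza sativa	420	382	90.95	12
chromosome	Populus trichocarpa	418	379	90.67	19
chromosome	Solanum lycopersicum	900	760	84.44	12
chromosome	Sorghum bicolor	730	659	90.27	10
chromosome	Vitis vinifera	487	426	87.47	19
chromosome	Zea mays	2300	2059	89.52	10
scaffold	Arabidopsis lyrata	207	207	100	695
scaffold	Carica papaya	372	343	92.2	5901
scaffold	Citrus clementina	NA	296	NA	1128
scaffold	Citrus sinensis	NA	319	NA	12574
scaffold	Cucumis sativus	367	203	55.31	4219
scaffold	Eucalyptus grandis	NA	691	NA	4952
scaffold	Gossypium raimondii	NA	764	NA	1448
scaffold	Linum usitatissimum	350	318	90.86	88420
scaffold	Manihot esculenta	760	533	70.13	12977
scaffold	Mimulus guttatus	430	322	74.88	2216
scaffold	Panicum virgatum	1400	1358	97	410030
scaffold	Phaseolus vulgaris	NA	487	NA	10132
scaffold	Physcomitrella patens	NA	480	NA	2106
scaffold	Prunus persica	230	227	98.7	202
scaffold	Ricinus communis	NA	351	NA	25828
scaffold	Selaginella moellendorffii	NA	213	NA	768
scaffold	Setaria italica	515	401	77.86	336
scaffold	Solanum tuberosum	840	734	87.38	68169
scaffold	Thellungiella halophila	NA	243	NA	639
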