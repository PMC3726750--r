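group	species	dbest_total	selected	printed_est_pct	matched	printed_accuracy_pct
chromosome	Arabidopsis thaliana	1529700	15297	1.00	14020	91.65
chromosome	Brachypodium distachyon	128092	1281	1.00	1259	98.28
chromosome	Fragaria vesca	10855	1086	10.00	958	88.21
chromosome	Glycine max	1461624	14616	1.00	14207	97.20
chromosome	Lotus japonicus	242432	2424	1.00	1283	52.93
chromosome	Malus x domestica	324847	3248	1.00	2957	91.04
chromosome	Medicago truncatula	269238	2692	1.00	1874	69.61
chromosome	Oryza sativa	1252989	12530	1.00	12016	95.90
chromosome	Populus trichocarpa	89943	8994	10.00	8726	97.02
chromosome	Solanum lycopersicum	298306	2983	1.00	2907	97.45
chromosome	Sorghum bicolor	209835	2098	1.00	2017	96.14
chromosome	Vitis vinifera	446639	4466	1.00	4099	91.78
chromosome	Zea mays	2019137	20191	1.00	19082	94.51
scaffold	Arabidopsis lyrata	561	548	100.00	523	95.44
scaffold	Carica papaya	77393	7739	10.00	6954	89.86
scaffold	Citrus clementina	117865	1179	1.00	1082	91.77
scaffold	Citrus sinensis	214142	2141	1.00	1906	89.02
scaffold	Cucumis sativus	8146	7396	100.00	7057	95.42
scaffold	Eucalyptus grandis	42576	4258	10.00	4004	94.03
scaffold	Gossypium raimondii	63577	6358	10.00	5875	92.40
scaffold	Linum usitatissimum	286852	2869	1.00	2827	98.54
scaffold	Manihot esculenta	80631	8063	10.00	7583	94.05
scaffold	Mimulus guttatus	231095	2311	1.00	2223	96.19
scaffold	Panicum virgatum	720590	7206	1.00	7003	97.18
scaffold	Phaseolus vulgaris	123988	1240	1.00	1148	92.58
scaffold	Physcomitrella patens	20456	2046	10.00	1960	95.80
scaffold	Prunus persica	79815	7982	10.00	7584	95.01
scaffold	Ricinus communis	62592	6259	10.00	6022	96.21
scaffold	Selaginella moellendorffii	93811	9381	10.00	9273	98.85
scaffold	Setaria italica	66027	6603	10.00	6092	92.26
scaffold	Solanum tuberosum	249920	2499	1.00	2442	97.72
scaffold	Thellungiella halophila	38022	3802	10.00	3739	98.34
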