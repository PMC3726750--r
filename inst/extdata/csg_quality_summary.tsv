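species	gc_pct	integrity_pct	accuracy_pct	segment_pct	level
Arabidopsis thaliana	35.97	95.20	91.65	93.40	1
Oryza sativa	42.41	90.95	95.90	72.82	1
Zea mays	46.60	89.52	94.51	97.38	1
Brachypodium distachyon	46.21	99.63	98.28	33.49	2
Populus trichocarpa	32.84	90.67	97.02	51.18	2
Vitis vinifera	33.67	87.47	91.78	40.34	2
Glycine max	34.21	86.36	97.20	41.13	2
Sorghum bicolor	41.56	90.27	96.14	18.31	3
Solanum lycopersicum	32.11	84.44	97.45	20.83	3
Fragaria vesca	35.78	81.25	88.21	31.06	3
Lotus japonicus	10.34	98.09	52.93	12.88	4
Medicago truncatula	27.39	94.48	69.61	37.29	4
Malus x domestica	27.62	70.89	91.04	33.40	4
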