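perturbagen	instance_id	score	reversed	aggravated
Vorinostat	6179	46	75	29
15d-PGJ2	1231	43	65	22
Piperlongumine	1764	36	55	19
Resveratrol	662	34	54	20
Ciclopirox	2456	33	67	34
Resveratrol	1715	32	59	27
LY-294002	6186	32	63	31
Valproic acid	410	31	53	22
Trichostatin A	1175	31	59	28
Ethoxyquin	3764	31	57	26
0173570-0000	7389	31	68	37
Parthenolide	1736	30	47	17
Ellipticine	1765	30	46	16
Etoposide	3241	30	73	43
Withaferin A	3819	30	68	38
Vorinostat	1161	29	57	28
Naproxen	2533	29	63	34
Rosiglitazone	2693	29	55	26
Monobenzone	3391	29	74	45
Alclometasone	5752	29	63	34
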