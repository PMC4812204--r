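rank	instance_id	perturbagen	dose	cell	score	up	down
1	1274	Bepridil	10 uM	HL60	-1	-0.077	0.223
2	7063	MG-262	100 nM	MCF7	-0.96	-0.163	0.125
3	7345	Alcuronium chloride	5 uM	MCF7	-0.953	-0.108	0.178
4	942	Prazosin	10 uM	MCF7	-0.953	-0.111	0.175
5	1764	Piperlongumine	13 uM	HL60	-0.94	-0.071	0.212
6	7022	Dyclonine	12 uM	MCF7	-0.931	-0.104	0.175
7	3351	(+/-)-Catechin	14 uM	MCF7	-0.923	-0.126	0.151
8	7017	Mesoridazine	7 uM	MCF7	-0.922	-0.101	0.176
9	909	HC toxin	100 nM	MCF7	-0.921	-0.107	0.17
10	1694	Metformin	24 uM	MCF7	-0.909	-0.102	0.17
11	1656	15d-PGJ2	10 uM	MCF7	-0.901	-0.112	0.158
12	7020	Xylometazoline	14 uM	MCF7	-0.898	-0.1	0.17
13	1058	Vorinostat	10 uM	MCF7	-0.898	-0.12	0.15
14	7178	Tetrandrine	6 uM	MCF7	-0.897	-0.151	0.118
15	1069	15d-PGJ2	10 uM	MCF7	-0.895	-0.12	0.149
16	1140	MG-132	21 uM	MCF7	-0.884	-0.122	0.143
17	1112	Trichostatin A	100 nM	MCF7	-0.882	-0.104	0.161
18	6936	Chlorpromazine	1 uM	MCF7	-0.88	-0.115	0.149
19	5310	Puromycin	7 uM	MCF7	-0.874	-0.111	0.151
20	5304	Moroxydine	19 uM	MCF7	-0.874	-0.125	0.137
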