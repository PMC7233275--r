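population	name	group	latitude	longitude	n	A	B	C	D	E
GAR	Garcia's pass	Langeberg	-33.96	21.22	24	0	0	0	24	0
OUT	Outeniqua Pass	Outeniqua W	-33.88	22.40	20	14	0	0	0	6
BP	Bergplaas MTO	Outeniqua W	-33.91	22.67	15	15	0	0	0	0
KNYS	Diepwalle Knysna	Outeniqua E	-33.92	23.14	15	15	0	0	0	0
PLETT	Plettenberg bay	Outeniqua E	-34.06	23.26	16	16	0	0	0	0
BKB	Bloukrans Bridge	Tsitsikamma	-33.97	23.65	18	14	0	4	0	0
LK	Langkloof	Tsitsikamma	-33.87	23.91	10	9	0	0	0	1
KP	Kareedouw pass	Tsitsikamma	-33.97	24.22	24	19	5	0	0	0
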