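section	species	category	reads	distinct	printedPctReads	printedPctDistinct
piRNA	Ae_aegypti	Total	11173973	5860037	100.00	100.00
piRNA	Ae_aegypti	TE	2177176	1240908	19.48	21.18
piRNA	Ae_aegypti	retrotransposon	1987059	1114018	17.78	19.01
piRNA	Ae_aegypti	DNA	113030	73584	1.01	1.26
piRNA	Ae_aegypti	MITE	29558	25324	0.26	0.43
piRNA	Ae_aegypti	other	47529	27982	0.43	0.48
piRNA	D_melanogaster	Total	271626	205307	100.00	100.00
piRNA	D_melanogaster	TE	135387	110068	49.84	53.61
piRNA	D_melanogaster	retrotransposon	129418	105485	47.65	51.38
piRNA	D_melanogaster	DNA	5969	4583	2.20	2.23
siRNA	Ae_aegypti	Total	765132	446834	100.00	100.00
siRNA	Ae_aegypti	TE	216859	154465	28.34	34.57
siRNA	Ae_aegypti	retrotransposon	133042	100067	17.39	22.39
siRNA	Ae_aegypti	DNA	28578	18692	3.74	4.18
siRNA	Ae_aegypti	MITE	32623	23667	4.26	5.30
siRNA	Ae_aegypti	other	22616	12039	2.96	2.69
siRNA	D_melanogaster	Total	86620	54049	100.00	100.00
siRNA	D_melanogaster	TE	15870	13280	18.32	24.57
siRNA	D_melanogaster	retrotransposon	15276	12720	17.64	23.53
siRNA	D_melanogaster	DNA	594	560	0.69	1.04
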