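gene	lengthBp	uniquePirnas	printedDensity	strandPercent	inCluster
AAEL011224	303	16488	54.6	100/0	yes
AAEL007866	1334	10651	8.0	99/1	yes
AAEL007861	1182	4356	3.7	100/0	yes
AAEL010454	1425	4084	2.9	90/10	yes
AAEL000120	1020	1432	1.4	94/6	no
AAEL009005	629	856	1.4	100/0	no
AAEL005277	4038	4891	1.2	100/0	yes
AAEL009525	1236	1494	1.2	100/0	no
AAEL005213	1377	1582	1.1	100/0	no
AAEL000668	1333	1522	1.1	100/0	no
AAEL001004	6251	7009	1.1	100/0	no
AAEL007686	2253	2439	1.1	100/0	no
AAEL001772	2562	2643	1.0	100/0	no
AAEL005456	966	841	0.9	100/0	yes
AAEL000808	978	811	0.8	100/0	yes
AAEL013013	1088	862	0.8	100/0	no
AAEL006843	21911	17268	0.8	100/0	no
AAEL006159	330	247	0.8	100/0	yes
AAEL005225	762	570	0.7	100/0	no
AAEL004959	1242	914	0.7	100/0	no
AAEL009873	1602	1142	0.7	78/22	no
AAEL005768	738	511	0.7	100/0	no
AAEL007499	579	372	0.6	100/0	no
AAEL007844	2572	1490	0.6	100/0	no
AAEL010887	60098	34174	0.6	100/0	no
AAEL000673	1461	753	0.5	100/0	no
AAEL000276	71446	36638	0.5	1/99	no
AAEL012346	1177	598	0.5	100/0	no
AAEL006704	1356	684	0.5	100/0	no
AAEL003715	615	298	0.5	100/0	no
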