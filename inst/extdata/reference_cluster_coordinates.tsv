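clusterId	contig	start	stop	printedSizeKb
1	supercont1.478	490638	568444	78
2	supercont1.1	1151499	1278727	127
3	supercont1.286	1260644	1444752	184
4	supercont1.943	196392	264127	68
5	supercont1.209	235416	285783	50
6	supercont1.20	3110107	3224809	115
7	supercont1.402	860224	953549	93
8	supercont1.1145	61909	94822	33
9	supercont1.435	926765	972082	45
10	supercont1.379	15854	108077	92
11	supercont1.555	368190	374829	7
12	supercont1.209	305189	366980	62
13	supercont1.109	91700	129810	38
14	supercont1.697	504405	552871	48
15	supercont1.164	1210657	1248495	38
16	supercont1.83	1415166	1433185	18
17	supercont1.41	2610658	2644427	34
18	supercont1.2	275115	329629	55
19	supercont1.38	3097699	3148574	51
20	supercont1.192	1700025	1763125	63
21	supercont1.38	2995043	3039699	45
22	supercont1.109	1912714	1927564	15
23	supercont1.194	895141	974760	80
24	supercont1.226	725419	748642	23
25	supercont1.518	151663	158105	6
26	supercont1.38	2572763	2684616	112
27	supercont1.90	907728	931721	24
28	supercont1.2	1423334	1464722	41
29	supercont1.192	551266	584318	33
30	supercont1.1	1420282	1453931	34
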