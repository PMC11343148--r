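transcript_id	RiboIP_Control_1	RiboInput_Control_1	RiboIP_Control_2	RiboInput_Control_2	RiboIP_Control_3	RiboInput_Control_3	RiboIP_Opto_1	RiboInput_Opto_1	RiboIP_Opto_2	RiboInput_Opto_2	RiboIP_Opto_3	RiboInput_Opto_3
g00001.t1	40	42	44	26	61	56	51	39	30	55	49	33
g00002.t1	1236	1124	1306	1122	1065	1271	883	1478	1171	901	1255	1583
g00003.t1	229	276	249	298	249	262	271	423	274	236	353	302
g00004.t1	1042	837	1497	1198	929	1301	722	1531	862	879	1701	845
g00005.t1	1222	474	975	1620	1036	765	1334	1287	872	1456	1244	1056
g00006.t1	3475	3986	2838	5654	4737	5317	6546	3112	6306	4908	7002	4196
g00007.t1	1095	1130	936	1160	1287	983	1603	1031	1218	781	824	1501
g00008.t1	2192	1460	3184	1541	1878	1835	1009	2290	446	2369	985	1441
g00009.t1	23	19	6	27	12	23	12	22	23	29	19	29
g00010.t1	2157	1283	1806	1902	1515	1864	946	1675	1211	1924	1554	2151
g00011.t1	200	151	204	206	255	199	191	192	143	140	183	176
g00012.t1	676	456	665	728	762	597	632	750	784	889	502	771
g00013.t1	3676	5496	5770	2246	4284	2231	2329	3850	3280	2731	3836	3670
g00014.t1	52	54	59	37	77	40	18	37	22	56	20	59
g00015.t1	1502	2054	1661	1347	1745	2096	995	1841	922	1603	1765	2010
g00016.t1	1925	1492	1363	1293	1647	1680	1975	2030	1274	1990	1937	1502
g00017.t1	1770	1033	1828	1471	1876	1228	2062	1833	1208	1300	1597	2194
g00018.t1	6	17	17	6	24	12	12	10	11	9	10	8
g00019.t1	196	166	172	159	142	199	159	276	223	298	135	160
g00020.t1	95	100	98	153	92	82	61	159	66	111	63	89
g00021.t1	702	672	773	845	839	878	284	682	262	721	254	828
g00022.t1	1017	996	1094	976	1456	1069	987	862	844	532	620	1131
g00023.t1	225	208	368	344	430	277	396	208	249	211	305	474
g00024.t1	422	417	354	282	352	406	460	315	381	439	472	337
g00025.t1	45	27	32	57	34	46	51	61	21	38	38	25
g00026.t1	187	98	117	96	99	145	187	165	210	128	230	94
g00027.t1	215	408	279	159	278	303	180	375	301	351	226	329
g00028.t1	3443	2225	1568	2172	3586	1792	2180	1564	1764	2823	2389	2578
g00029.t1	69	158	123	81	82	72	112	135	86	71	48	82
g00030.t1	2973	1692	2040	2385	2069	1277	1872	1653	2158	2009	1489	3188
g00031.t1	59	130	61	69	101	85	100	91	102	110	82	67
g00032.t1	984	850	1364	427	636	810	554	684	583	424	600	677
g00033.t1	1074	916	1543	1270	1175	954	1771	943	874	1548	1869	1134
g00034.t1	4041	2882	3793	3070	2427	2679	2339	2812	1758	2349	2834	2739
g00035.t1	602	365	594	570	425	506	379	468	443	390	595	359
g00036.t1	293	244	259	335	218	366	229	345	295	226	283	266
g00037.t1	72	61	51	41	76	47	65	61	44	86	77	83
g00038.t1	175	162	221	239	124	152	214	195	129	198	106	206
g00039.t1	1372	1068	646	1459	744	1657	1128	780	1143	581	1163	656
g00040.t1	1162	1500	1331	1335	2075	1375	1479	1255	1317	1212	1274	1000
g00041.t1	627	1049	576	583	603	526	565	536	602	859	586	542
g00042.t1	124	103	129	88	153	156	228	239	261	121	299	99
g00043.t1	438	374	346	503	416	535	195	542	207	542	210	482
g00044.t1	382	282	527	516	338	523	359	502	312	364	274	494
g00045.t1	675	1007	1060	563	570	701	546	534	407	836	661	507
g00046.t1	3907	6807	3822	4091	3590	3999	4462	4689	3063	3734	2167	3665
g00047.t1	3865	5272	3838	4875	4185	4593	3142	4276	4557	3629	4797	2707
g00048.t1	876	1644	1528	1302	1096	989	1975	1700	2099	1557	2530	986
g00049.t1	433	230	424	324	286	521	922	391	590	387	582	282
g00050.t1	31	36	40	56	41	48	34	44	27	27	40	26
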