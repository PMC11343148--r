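transcript_id	CLIP_Control_1	CLIP_Control_2	CLIP_Control_3	CLIP_Control_4	CLIP_Opto_1	CLIP_Opto_2	CLIP_Opto_3	CLIP_Opto_4
g00001.t1	12	10	25	21	14	10	21	13
g00002.t1	447	432	471	414	417	561	171	440
g00003.t1	565	525	993	426	532	533	866	1029
g00004.t1	299	391	181	402	238	169	206	517
g00005.t1	261	182	189	735	307	316	343	381
g00006.t1	1040	1079	1103	1160	1993	2778	3880	2277
g00007.t1	234	321	183	406	444	188	870	321
g00008.t1	528	1020	711	690	198	161	224	326
g00009.t1	29	18	25	40	48	32	58	39
g00010.t1	465	691	476	618	420	470	480	288
g00011.t1	56	63	148	73	73	51	61	77
g00012.t1	374	225	609	335	1549	956	1683	2065
g00013.t1	1672	2439	1707	4270	6860	7956	6664	6712
g00014.t1	20	44	36	48	34	28	62	85
g00015.t1	874	367	340	617	290	258	527	408
g00016.t1	370	781	773	518	415	464	594	852
g00017.t1	3712	3815	5094	2261	3811	3769	4172	4620
g00018.t1	4	6	2	6	5	9	6	7
g00019.t1	46	45	47	44	55	33	53	60
g00020.t1	14	18	22	29	11	28	37	33
g00021.t1	133	269	161	237	127	99	105	126
g00022.t1	182	251	219	252	286	269	285	480
g00023.t1	111	97	107	104	97	85	119	171
g00024.t1	165	145	136	147	171	131	321	246
g00025.t1	11	10	10	15	11	10	24	5
g00026.t1	35	68	50	30	124	29	64	78
g00027.t1	25	104	29	83	108	47	75	154
g00028.t1	719	481	736	1188	527	612	1266	801
g00029.t1	14	18	28	25	36	27	19	12
g00030.t1	853	347	756	322	680	458	1125	564
g00031.t1	228	220	128	320	312	122	220	462
g00032.t1	2161	2254	1883	3898	1088	650	1794	1979
g00033.t1	442	671	1025	1121	2472	3342	3161	3934
g00034.t1	5306	4667	8924	8594	1968	543	1216	1928
g00035.t1	813	1040	1131	726	3109	1125	1557	852
g00036.t1	231	231	195	221	672	355	841	550
g00037.t1	111	177	198	199	50	43	48	38
g00038.t1	59	35	56	102	35	37	52	35
g00039.t1	330	185	302	936	435	379	307	593
g00040.t1	3781	4337	5554	2397	317	998	606	1122
g00041.t1	139	128	162	177	194	231	223	192
g00042.t1	26	35	47	23	111	61	170	96
g00043.t1	901	854	843	1286	579	366	395	1048
g00044.t1	215	136	90	54	87	55	170	251
g00045.t1	1177	1182	1008	2680	477	285	601	261
g00046.t1	17526	12371	9586	7644	9313	15855	7704	6609
g00047.t1	990	1875	784	1377	1440	783	1276	969
g00048.t1	1533	3447	1913	2048	6879	3726	4832	5219
g00049.t1	685	1781	756	555	530	420	353	551
g00050.t1	76	112	48	126	51	87	93	124
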