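transcript_id	gene_id	length	base_abundance	beta_control	delta	ribo_log2fc	truth_class	quadrant_truth	marker_set	is_primary
g00001.t1	g00001	1391	1.275940743	0	0	0	nontarget	unchanged	NA	TRUE
g00002.t1	g00002	2223	5.338839301	0	0	0	nontarget	unchanged	NA	TRUE
g00003.t1	g00003	1279	4.069871331	3	0	0	stringent_both	unchanged	NA	TRUE
g00004.t1	g00004	2099	5.339210122	0	0	0	nontarget	unchanged	NA	TRUE
g00005.t1	g00005	1965	5.406071685	0	0	0	nontarget	unchanged	NA	TRUE
g00006.t1	g00006	3824	6.264767314	0	0	1	nontarget	fmrp_unchanged_ribo_up	NA	TRUE
g00007.t1	g00007	2951	4.932181924	0	0	0	nontarget	unchanged	NA	TRUE
g00008.t1	g00008	1672	6.509149502	0	0	-1	nontarget	fmrp_unchanged_ribo_down	NA	TRUE
g00009.t1	g00009	1653	-0.1582055571	3	0	0	stringent_both	unchanged	NA	TRUE
g00010.t1	g00010	1092	6.902978487	0	0	0	nontarget	unchanged	NA	TRUE
g00011.t1	g00011	2358	2.760508484	0	0	0	nontarget	unchanged	NA	TRUE
g00012.t1	g00012	2004	4.691609156	1	2	0	opto_only	fmrp_up_ribo_unchanged	NA	TRUE
g00013.t1	g00013	3206	6.319729577	1	2	0	opto_only	fmrp_up_ribo_unchanged	NA	TRUE
g00014.t1	g00014	2577	0.7106611637	1	2	-1	opto_only	fmrp_up_ribo_down	NA	TRUE
g00015.t1	g00015	3444	5.298591277	0	0	0	nontarget	unchanged	NA	TRUE
g00016.t1	g00016	3181	5.372146521	0	0	0	nontarget	unchanged	NA	TRUE
g00017.t1	g00017	1976	5.968892018	3	0	0	stringent_both	unchanged	NA	TRUE
g00018.t1	g00018	1763	-0.6910380174	0	0	0	nontarget	unchanged	NA	TRUE
g00019.t1	g00019	1554	3.333697221	0	0	0	nontarget	unchanged	NA	TRUE
g00020.t1	g00020	2207	1.935987821	0	0	-1	nontarget	fmrp_unchanged_ribo_down	NA	TRUE
g00021.t1	g00021	1517	5.200039055	0	0	-1	nontarget	fmrp_unchanged_ribo_down	NA	TRUE
g00022.t1	g00022	1712	5.5592845	0	0	0	nontarget	unchanged	NA	TRUE
g00023.t1	g00023	3225	2.800090848	0	0	0	nontarget	unchanged	NA	TRUE
g00024.t1	g00024	2380	3.700316662	0	0	0	nontarget	unchanged	NA	TRUE
g00025.t1	g00025	1504	1.11690982	0	0	0	nontarget	unchanged	NA	TRUE
g00026.t1	g00026	2197	1.838883738	0	0	1	nontarget	fmrp_unchanged_ribo_up	NA	TRUE
g00027.t1	g00027	1626	3.734117847	0	0	0	nontarget	unchanged	NA	TRUE
g00028.t1	g00028	4220	5.578687489	0	0	0	nontarget	unchanged	NA	TRUE
g00029.t1	g00029	3015	1.305128341	0	0	0	nontarget	unchanged	NA	TRUE
g00030.t1	g00030	2597	5.949077901	0	0	0	nontarget	unchanged	NA	TRUE
g00031.t1	g00031	1845	2.053272371	3	0	0	stringent_both	unchanged	NA	TRUE
g00032.t1	g00032	2062	4.685976366	3	0	0	stringent_both	unchanged	NA	TRUE
g00033.t1	g00033	931	6.773040146	1	2	0	opto_only	fmrp_up_ribo_unchanged	NA	TRUE
g00034.t1	g00034	1699	6.86807049	3	-2	0	control_only	fmrp_down_ribo_unchanged	NA	TRUE
g00035.t1	g00035	3608	3.402170879	3	0	0	stringent_both	unchanged	NA	TRUE
g00036.t1	g00036	1639	3.765862304	1	2	0	opto_only	fmrp_up_ribo_unchanged	NA	TRUE
g00037.t1	g00037	1968	1.274246595	3	-2	0	control_only	fmrp_down_ribo_unchanged	NA	TRUE
g00038.t1	g00038	1893	2.940160079	0	0	0	nontarget	unchanged	NA	TRUE
g00039.t1	g00039	3504	4.571447959	0	0	0	nontarget	unchanged	NA	TRUE
g00040.t1	g00040	2617	5.242618882	3	-2	0	control_only	fmrp_down_ribo_unchanged	NA	TRUE
g00041.t1	g00041	1527	5.165213157	0	0	0	nontarget	unchanged	NA	TRUE
g00042.t1	g00042	1604	2.839660271	0	0	1	nontarget	fmrp_unchanged_ribo_up	NA	TRUE
g00043.t1	g00043	1496	4.650316446	3	0	-1	stringent_both	fmrp_unchanged_ribo_down	NA	TRUE
g00044.t1	g00044	1626	4.203328613	0	0	0	nontarget	unchanged	NA	TRUE
g00045.t1	g00045	2819	4.166164176	3	-2	0	control_only	fmrp_down_ribo_unchanged	NA	TRUE
g00046.t1	g00046	1587	7.595567442	3	0	0	stringent_both	unchanged	NA	TRUE
g00047.t1	g00047	1526	7.833697755	0	0	0	nontarget	unchanged	NA	TRUE
g00048.t1	g00048	987	6.823568476	3	0	1	stringent_both	fmrp_unchanged_ribo_up	NA	TRUE
g00049.t1	g00049	1659	4.160147639	3	-2	1	control_only	fmrp_down_ribo_up	NA	TRUE
g00050.t1	g00050	2329	0.3918334467	3	0	0	stringent_both	unchanged	NA	TRUE
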