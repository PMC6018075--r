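spot_id	volume_norm	protein_id	category	minor_flag
31	2.3606	AKC91211	alpha	FALSE
34	0.7751	AKC91203	alpha	FALSE
35	1.1837	AKB95609	alpha	FALSE
52	0.6117	AKB95609	alpha	TRUE
46	0.4864	AKC91236	alpha	FALSE
47	1.0729	AKC91207	alpha	FALSE
62	0.8574	AKC91207	alpha	TRUE
50	0.7207	ABQ52124	alpha	FALSE
51	3.0831	ABQ52124	alpha	FALSE
59	0.593	AFX69641	alpha	TRUE
63	1.1036	AKC91229	alpha	FALSE
91	0.4951	AFF27490	alpha	FALSE
19	0.3613	BAM08461	alpha	FALSE
21	2.3026	BAM08459	alpha	FALSE
25	1.9692	BAM08459	alpha	FALSE
26	1.8786	BU-alpha23	alpha	FALSE
39	1.5257	BU-alpha23	alpha	FALSE
27	1.9574	BAM08455	alpha	FALSE
38	0.6331	BU-alpha12	alpha	FALSE
40	0.9367	BU-alpha8	alpha	FALSE
43	2.9852	BAM08454	alpha	TRUE
57	2.3871	BAS02443	alpha	TRUE
29	2.7417	ACX71610	alpha	FALSE
30	1.4238	BU-alpha4	alpha	FALSE
33	1.3789	BU-alpha4	alpha	FALSE
32	0.8802	AFX69619	alpha	FALSE
44	0.2249	AFX69619	alpha	FALSE
36	0.5626	BU-alpha10	alpha	FALSE
37	1.5034	BU-alpha3	alpha	FALSE
43	2.9852	BU-alpha3	alpha	FALSE
45	1.7178	AFQ13463	alpha	FALSE
53	2.0238	BU-alpha1	alpha	FALSE
54	0.7489	BU-alpha1	alpha	FALSE
58	0.8343	ABS72161	alpha	TRUE
92	0.6939	ABD85199	alpha	FALSE
23	0.6495	AFX69625	alpha	FALSE
28	1.6096	AFX69606	alpha	FALSE
24	0.2507	AGJ50340	gamma	FALSE
41	0.9768	AGJ50340	gamma	FALSE
64	0.4177	ACJ03455	gamma	FALSE
66	1.0841	BU-gamma6	gamma	FALSE
67	0.7739	ACJ03500	gamma	FALSE
10	0.9077	BU-gamma5	gamma	FALSE
11	0.4282	BU-gamma5	gamma	FALSE
13	1.6965	BU-gamma5	gamma	FALSE
14	1.0943	BU-gamma5	gamma	FALSE
15	0.7993	BU-gamma5	gamma	FALSE
16	0.8937	BU-gamma5	gamma	FALSE
17	1.1153	BU-gamma5	gamma	FALSE
56	0.7993	BU-gamma5	gamma	FALSE
57	2.3871	BU-gamma5	gamma	TRUE
95	1.7696	BU-gamma5	gamma	FALSE
96	0.6516	BU-gamma5	gamma	FALSE
60	1.0594	BU-gamma7	gamma	FALSE
61	1.5728	BU-gamma7	gamma	FALSE
93	0.4481	BU-gamma7	gamma	FALSE
94	0.8863	BU-gamma7	gamma	FALSE
70	1.6662	BU-gamma9	gamma	FALSE
52	0.6117	BU-gamma10	gamma	FALSE
43	2.9852	ACI04085	gamma	TRUE
58	0.8343	BU-gamma2	gamma	FALSE
73	0.8551	BU-gamma2	gamma	FALSE
48	0.2889	AAD30440	gamma	FALSE
49	0.3394	AAD30440	gamma	FALSE
59	0.593	BU-gamma4	gamma	FALSE
62	0.8574	BU-gamma4	gamma	FALSE
65	1.1687	BU-gamma4	gamma	FALSE
97	0.45	ADF58069	omega	FALSE
77	0.4747	AAS10189	lmw_gs	FALSE
96	0.6516	AAS10187	lmw_gs	TRUE
74	1.6289	AEI00658	lmw_gs	FALSE
78	1.3864	ACA63869	lmw_gs	FALSE
16	0.8937	BU-LMW-PCR2	lmw_gs	TRUE
55	0.5465	BU-LMW-PCR2	lmw_gs	FALSE
57	2.3871	BU-LMW-PCR2	lmw_gs	FALSE
46	0.4864	AAP44989	lmw_gs	TRUE
56	0.7993	ABY58134	lmw_gs	TRUE
76	1.3898	ABY58134	lmw_gs	FALSE
68	1.1408	AAV92011	lmw_gs	FALSE
69	0.5626	AAV92011	lmw_gs	FALSE
71	0.9754	BU-LMW-PCR3	lmw_gs	FALSE
72	0.5433	BU-LMW-PCR3	lmw_gs	FALSE
95	1.7696	ACY08820	lmw_gs	TRUE
75	0.9145	ABC84366	lmw_gs	FALSE
79	0.314	BQ804660	non_gluten	FALSE
80	1.1677	BQ838917	non_gluten	FALSE
81	1.5259	BQ804472	non_gluten	FALSE
48	0.2889	AHA61701	non_gluten	TRUE
82	0.5308	AveninLike-BU2	non_gluten	FALSE
89	1.0783	CDM81434	non_gluten	FALSE
90	1.1652	CAA39099	non_gluten	FALSE
84	0.4981	AGH06195	non_gluten	FALSE
1	1.2544		unknown	FALSE
2	0.7294		unknown	FALSE
3	0.6666		unknown	FALSE
4	1.6465		unknown	FALSE
5	1.1273		unknown	FALSE
6	0.3483		unknown	FALSE
7	0.5235		unknown	FALSE
8	0.0754		unknown	FALSE
9	0.2195		unknown	FALSE
12	0.595		unknown	FALSE
18	0.1939		unknown	FALSE
20	0.6581		unknown	FALSE
22	0.6766		unknown	FALSE
42	0.3517		unknown	FALSE
83	1.483		unknown	FALSE
85	0.4911		unknown	FALSE
86	0.5405		unknown	FALSE
87	0.3504		unknown	FALSE
88	1.8445		unknown	FALSE
98	0.7143		unknown	FALSE
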