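protein_id	res_cold_1	res_cold_2	res_cold_3	res_control_1	res_control_2	res_control_3	sus_cold_1	sus_cold_2	sus_cold_3	sus_control_1	sus_control_2	sus_control_3
SYN_P00001	6	6	7	3	4	7	8	6	5	1	4	9
SYN_P00002	0	0	0	0	0	0	0	0	0	0	0	0
SYN_P00003	29	33	24	39	48	71	3	4	6	30	36	39
SYN_P00004	2	1	1	9	6	0	4	2	3	1	5	2
SYN_P00005	0	0	0	1	0	2	4	5	0	1	1	1
SYN_P00006	0	0	3	0	0	0	0	0	0	0	0	0
SYN_P00007	8	6	3	7	4	8	6	6	5	5	5	6
SYN_P00008	0	0	0	1	2	0	0	0	0	0	1	0
SYN_P00009	0	2	1	4	4	2	6	4	3	8	4	6
SYN_P00010	21	38	27	53	54	53	161	110	160	41	40	35
SYN_P00011	4	0	4	6	1	7	4	0	5	4	4	0
SYN_P00012	1	2	0	1	0	1	4	0	0	1	0	0
SYN_P00013	2	1	0	4	4	3	1	1	2	4	0	1
SYN_P00014	0	0	0	0	3	0	0	2	1	0	0	0
SYN_P00015	9	8	11	20	4	14	9	13	17	13	9	9
SYN_P00016	470	384	367	112	71	70	89	95	108	88	97	47
SYN_P00017	0	0	0	0	0	0	0	2	0	1	0	0
SYN_P00018	2	2	1	1	1	3	1	2	3	1	3	0
SYN_P00019	3	0	0	1	6	0	1	0	3	1	4	1
SYN_P00020	20	37	36	41	42	26	33	40	59	36	39	27
SYN_P00021	1	0	0	3	0	4	0	0	2	0	1	1
SYN_P00022	8	5	11	8	7	5	7	6	14	4	12	3
SYN_P00023	0	0	0	0	0	0	0	0	0	0	0	0
SYN_P00024	416	480	430	247	227	184	167	188	243	125	190	162
SYN_P00025	6	7	11	75	47	49	39	38	37	40	70	45
SYN_P00026	1	3	0	1	1	4	0	0	0	2	0	7
SYN_P00027	0	0	0	0	0	0	0	0	0	0	0	0
SYN_P00028	4	8	9	5	4	4	7	3	10	5	11	3
SYN_P00029	9	3	8	17	20	2	11	16	14	8	11	16
SYN_P00030	1	0	1	8	0	2	1	0	2	1	2	2
SYN_P00031	11	3	8	4	1	13	6	2	9	1	7	9
SYN_P00032	0	1	1	5	1	0	2	1	1	3	0	0
SYN_P00033	6	11	9	17	10	13	8	6	14	9	10	21
SYN_P00034	4	3	1	2	4	4	5	6	2	1	4	6
SYN_P00035	0	3	1	2	2	0	3	2	3	1	5	2
SYN_P00036	0	0	0	0	0	0	0	0	0	0	0	0
SYN_P00037	5	6	13	10	12	14	4	10	9	7	5	9
SYN_P00038	5	6	7	8	4	0	2	6	4	8	14	6
SYN_P00039	0	0	0	0	0	0	0	0	0	0	0	0
SYN_P00040	0	0	0	1	0	0	0	0	0	0	0	0
SYN_P00041	8	4	4	7	4	5	6	7	3	7	8	7
SYN_P00042	0	1	0	0	0	0	2	1	1	1	0	1
SYN_P00043	6	6	7	12	8	10	12	7	4	6	13	12
SYN_P00044	0	0	0	0	0	0	0	0	0	0	0	0
SYN_P00045	0	0	0	0	0	0	0	2	1	0	0	0
SYN_P00046	36	21	24	28	37	66	28	45	24	28	34	21
SYN_P00047	1	0	3	1	3	5	8	6	7	4	5	1
SYN_P00048	13	18	18	25	14	15	21	23	18	16	19	16
SYN_P00049	77	112	97	91	93	71	73	91	105	88	108	130
SYN_P00050	6	3	7	6	7	5	4	10	5	9	5	6
SYN_P00051	0	0	0	0	0	0	0	0	0	0	0	0
SYN_P00052	2	5	4	6	2	7	1	6	5	5	5	5
SYN_P00053	54	65	67	81	81	62	78	83	62	64	109	59
SYN_P00054	214	217	160	211	367	240	358	243	272	541	374	382
SYN_P00055	0	0	0	0	0	0	0	0	0	0	0	0
SYN_P00056	0	0	0	0	0	0	12	6	11	0	0	0
SYN_P00057	0	0	0	0	3	2	0	0	0	0	0	0
SYN_P00058	0	0	0	0	0	0	0	0	0	1	0	0
SYN_P00059	0	0	0	0	0	0	0	0	0	0	0	2
SYN_P00060	2	1	0	4	2	2	1	2	2	0	6	4
SYN_P00061	0	0	0	0	0	0	0	0	0	0	0	0
SYN_P00062	141	167	127	299	260	241	231	200	121	148	176	262
SYN_P00063	3	1	3	3	3	6	7	6	7	2	7	7
SYN_P00064	2	6	3	7	1	8	7	7	10	0	11	4
SYN_P00065	4	8	2	10	9	4	4	6	4	8	11	7
SYN_P00066	4	5	6	6	9	4	7	5	7	2	14	8
SYN_P00067	1	8	7	4	5	1	5	0	0	4	6	5
SYN_P00068	71	76	102	127	108	103	144	105	130	109	158	128
SYN_P00069	4	3	1	4	1	3	3	2	5	6	6	6
SYN_P00070	0	0	0	0	0	0	0	0	0	0	1	0
SYN_P00071	1	2	4	5	3	3	6	3	4	8	7	5
SYN_P00072	0	0	1	1	0	0	1	1	0	0	2	0
SYN_P00073	1	1	1	1	1	1	0	2	1	2	0	0
SYN_P00074	0	0	0	0	0	0	0	0	0	0	0	0
SYN_P00075	5	5	5	8	3	6	4	6	4	8	5	3
SYN_P00076	0	2	3	5	4	4	4	8	2	4	4	4
SYN_P00077	12	9	17	10	11	19	8	11	11	11	11	9
SYN_P00078	0	2	3	1	4	4	5	1	3	3	6	5
SYN_P00079	0	0	0	0	0	0	0	0	0	0	0	0
SYN_P00080	131	121	178	24	26	25	20	28	15	20	29	31
SYN_P00081	2	5	2	3	5	5	6	4	10	1	2	5
SYN_P00082	14	18	25	20	15	19	14	16	22	34	31	30
SYN_P00083	0	0	0	0	0	0	0	0	0	0	0	0
SYN_P00084	0	0	1	2	0	0	0	1	2	0	0	1
SYN_P00085	1	0	0	1	0	0	0	0	0	0	0	1
SYN_P00086	4	1	0	2	1	2	3	2	0	2	2	2
SYN_P00087	45	37	36	59	42	43	48	33	41	64	35	38
SYN_P00088	3	4	0	2	1	5	4	3	2	2	5	0
SYN_P00089	1	9	3	4	8	17	10	7	11	8	17	11
SYN_P00090	0	1	0	0	0	0	1	0	0	0	1	1
SYN_P00091	4	5	4	1	2	0	1	1	3	1	0	4
SYN_P00092	32	17	15	13	19	21	17	29	18	17	13	33
SYN_P00093	47	30	39	81	76	63	43	67	43	58	67	90
SYN_P00094	63	68	49	127	75	117	58	103	55	80	76	69
SYN_P00095	0	0	0	0	0	0	0	0	0	0	0	0
SYN_P00096	90	168	102	133	115	99	120	106	168	118	119	115
SYN_P00097	13	7	10	10	8	22	11	21	10	15	12	13
SYN_P00098	5	2	0	0	1	2	1	0	2	0	2	1
SYN_P00099	8	14	8	13	14	9	10	11	18	11	14	10
SYN_P00100	0	0	0	0	0	0	1	0	0	0	0	0
SYN_P00101	0	0	0	1	0	0	0	0	0	0	0	0
SYN_P00102	3	8	3	11	7	6	3	2	7	7	6	5
SYN_P00103	0	0	0	0	0	0	0	0	0	0	0	0
SYN_P00104	8	11	12	8	14	18	10	9	10	13	17	12
SYN_P00105	37	16	19	36	27	31	14	39	32	27	37	31
SYN_P00106	0	0	0	1	0	0	0	0	0	0	0	0
SYN_P00107	2	0	2	0	0	0	0	0	0	0	0	0
SYN_P00108	10	13	10	7	2	0	7	5	2	3	2	2
SYN_P00109	0	0	0	0	0	0	0	1	0	0	0	0
SYN_P00110	0	1	1	1	4	1	0	1	0	5	1	0
SYN_P00111	8	13	19	32	20	24	25	22	12	13	20	16
SYN_P00112	11	10	15	35	28	41	18	36	17	30	19	21
SYN_P00113	2	6	4	11	8	11	6	6	2	10	7	10
SYN_P00114	0	0	0	0	0	0	0	0	0	0	0	0
SYN_P00115	0	1	2	1	1	0	0	1	1	0	0	0
SYN_P00116	16	13	18	27	26	26	14	30	13	23	22	18
SYN_P00117	9	10	6	12	16	15	7	12	11	10	13	18
SYN_P00118	6	11	10	8	6	16	9	11	10	11	11	8
SYN_P00119	0	0	0	0	0	0	0	0	0	0	0	0
SYN_P00120	2	4	2	5	1	6	4	7	4	4	7	5
SYN_P00121	1	6	7	3	9	4	0	5	3	2	4	8
SYN_P00122	2	0	1	1	3	3	2	0	1	3	1	1
SYN_P00123	4	1	3	7	9	13	10	1	6	6	2	8
SYN_P00124	6	5	0	4	5	4	5	2	9	6	3	3
SYN_P00125	2	1	0	2	4	0	0	0	0	1	1	0
SYN_P00126	18	16	40	49	35	40	19	47	37	30	47	36
SYN_P00127	4	3	5	5	8	4	0	6	5	2	9	7
SYN_P00128	0	0	0	0	0	0	0	0	0	0	0	0
SYN_P00129	29	21	35	26	23	35	24	24	23	26	17	36
SYN_P00130	25	28	37	42	37	25	29	14	29	50	38	41
SYN_P00131	18	16	16	18	21	30	21	31	13	20	28	25
SYN_P00132	0	0	1	0	0	0	0	0	0	0	0	0
SYN_P00133	0	1	0	2	0	2	0	0	1	0	0	0
SYN_P00134	22	16	13	13	21	27	24	21	13	15	16	21
SYN_P00135	4	4	7	7	5	4	224	194	164	6	6	7
SYN_P00136	15	16	14	1	5	10	1	0	0	3	4	7
SYN_P00137	253	190	338	211	313	417	218	247	192	232	279	317
SYN_P00138	0	0	0	1	2	1	0	0	0	0	2	1
SYN_P00139	0	0	0	0	0	0	0	0	0	0	0	0
SYN_P00140	6	3	2	10	6	9	5	10	5	5	5	8
SYN_P00141	2	0	0	0	0	1	0	0	0	0	1	0
SYN_P00142	4	3	7	3	7	3	9	7	7	7	3	2
SYN_P00143	0	0	0	0	0	0	0	0	0	0	0	0
SYN_P00144	260	191	173	179	245	223	249	267	331	410	206	254
SYN_P00145	0	3	0	4	0	1	3	2	2	1	4	3
SYN_P00146	2	1	3	2	0	2	3	0	3	2	0	1
SYN_P00147	0	0	1	0	2	4	2	3	3	0	3	1
SYN_P00148	9	10	12	19	12	10	8	9	11	16	8	15
SYN_P00149	1	11	2	7	7	5	3	10	3	8	8	2
SYN_P00150	0	0	0	0	0	0	0	0	0	0	0	0
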