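protein_id	length	abundance	fold_resistant	fold_susceptible
SYN_P00001	496	0.9218276990250968	1	1
SYN_P00002	189	0.04491023116077706	1	1
SYN_P00003	300	10.322635428922018	1	0.1477041703999853
SYN_P00004	343	0.5785146533593225	1	1
SYN_P00005	306	0.39231481997031986	1	1
SYN_P00006	237	0.08403644913566345	1	1
SYN_P00007	532	0.9845958096531083	1	1
SYN_P00008	238	0.20178260864859482	1	1
SYN_P00009	686	0.34404436568818175	1	1
SYN_P00010	242	13.135920375840122	1	3.6243109572622876
SYN_P00011	480	0.7039473303375823	1	1
SYN_P00012	784	0.11723617743313612	1	1
SYN_P00013	125	1.3859887237814064	1	1
SYN_P00014	217	0.4840936829140996	1	1
SYN_P00015	234	3.2544623845253415	1	1
SYN_P00016	344	17.546313229702896	5.532161082145244	1
SYN_P00017	217	0.1373277297095506	1	1
SYN_P00018	66	2.482585593665078	1	1
SYN_P00019	74	1.1850632128682677	1	1
SYN_P00020	484	5.996231355858597	1	1
SYN_P00021	214	0.6315638221722131	1	1
SYN_P00022	103	5.329397204391827	1	1
SYN_P00023	229	0.030497464722586076	1	1
SYN_P00024	459	29.33900450810415	3.3085318609798007	1
SYN_P00025	645	5.638149771767721	0.14271255430593702	1
SYN_P00026	202	0.7396693789894806	1	1
SYN_P00027	220	0.05513259040467085	1	1
SYN_P00028	104	3.618347392111923	1	1
SYN_P00029	315	2.628432675388896	1	1
SYN_P00030	182	0.9873691939112058	1	1
SYN_P00031	314	1.3537950351269536	1	1
SYN_P00032	356	0.31092052667421094	1	1
SYN_P00033	419	2.09093945558259	1	1
SYN_P00034	184	1.802741712100007	1	1
SYN_P00035	322	0.5720557961257906	1	1
SYN_P00036	106	0.06908115474522192	1	1
SYN_P00037	169	4.061277733879112	1	1
SYN_P00038	163	3.029486837290858	1	1
SYN_P00039	75	0.18775578330257836	1	1
SYN_P00040	255	0.04120579719072261	1	1
SYN_P00041	277	1.5066929672684022	1	1
SYN_P00042	209	0.5014878215385088	1	1
SYN_P00043	365	1.6573557435294497	1	1
SYN_P00044	174	0.075169859644485	1	1
SYN_P00045	126	0.14685040127944868	1	5.440647039039491
SYN_P00046	310	8.771867340329212	1	1
SYN_P00047	167	2.242406925804336	1	1
SYN_P00048	515	3.23159257642606	1	1
SYN_P00049	201	37.730051249889335	1	1
SYN_P00050	347	1.2938766373778385	1	1
SYN_P00051	294	0.01828163133416107	1	1
SYN_P00052	169	1.94946386718406	1	1
SYN_P00053	550	10.408785974260322	1	1
SYN_P00054	345	61.50254060432298	1	1
SYN_P00055	261	0.06369028775957405	1	1
SYN_P00056	287	0.10008743437556769	1	33.452130280033174
SYN_P00057	351	0.2437425363878549	1	1
SYN_P00058	261	0.12146713286999665	1	1
SYN_P00059	56	0.274861636952968	1	1
SYN_P00060	288	0.6902123774435817	1	1
SYN_P00061	208	0.0904965001427397	1	1
SYN_P00062	274	58.78838691578057	1	1
SYN_P00063	334	1.2405433756116386	1	1
SYN_P00064	503	0.8451710880865223	1	1
SYN_P00065	174	2.694571741526539	1	1
SYN_P00066	479	1.0777013273126064	1	1
SYN_P00067	296	0.7678383314550725	1	1
SYN_P00068	420	19.174376819767282	1	1
SYN_P00069	396	0.6478731096901341	1	1
SYN_P00070	358	0.07674980692259956	1	1
SYN_P00071	148	2.1626531559718076	1	1
SYN_P00072	239	0.4950850331336889	1	1
SYN_P00073	341	0.35218728447381975	1	1
SYN_P00074	155	0.11809541242427324	1	1
SYN_P00075	191	2.3554500341927707	1	1
SYN_P00076	334	0.7060731260671074	1	1
SYN_P00077	367	2.804809037392126	1	1
SYN_P00078	315	0.6257961783358728	1	1
SYN_P00079	161	0.2679360753748482	1	1
SYN_P00080	144	12.188260180427072	7.964141702551949	1
SYN_P00081	533	0.5806962698166244	1	1
SYN_P00082	284	6.658564972563903	1	1
SYN_P00083	261	0.0904312975000219	1	1
SYN_P00084	235	0.3936739726767681	1	1
SYN_P00085	138	0.5835046895786837	1	0.08213776698009313
SYN_P00086	339	0.4575217674550362	1	1
SYN_P00087	224	14.841302805047162	1	1
SYN_P00088	228	0.9554915082273469	1	1
SYN_P00089	399	1.6297908638605036	1	1
SYN_P00090	377	0.15186802137643385	1	1
SYN_P00091	501	0.23260011301534889	2.101649637731024	1
SYN_P00092	197	7.360573251278559	1	1
SYN_P00093	346	12.39091235327485	1	1
SYN_P00094	501	12.15483918861613	1	1
SYN_P00095	143	0.06321117972751078	1	1
SYN_P00096	163	60.33554426923862	1	1
SYN_P00097	142	7.642659613874793	1	1
SYN_P00098	121	0.9479676248840015	1	1
SYN_P00099	260	4.084566315650104	1	1
SYN_P00100	347	0.14330637496328258	0.12383737060926898	1
SYN_P00101	456	0.1116582420368121	1	1
SYN_P00102	422	1.1030740817367193	1	1
SYN_P00103	151	0.09099126981962147	1	1
SYN_P00104	630	1.4623401530921292	1	1
SYN_P00105	179	13.402105201534145	1	1
SYN_P00106	264	0.12647034237508348	1	1
SYN_P00107	202	0.228348682635524	1	1
SYN_P00108	235	1.097602086443261	4.988455019694729	1
SYN_P00109	275	0.13065536294808233	1	1
SYN_P00110	265	0.4646048963863233	1	1
SYN_P00111	247	5.728827146740489	1	1
SYN_P00112	264	6.952421581903328	1	1
SYN_P00113	196	2.1547901272245076	1	1
SYN_P00114	194	0.02464672305847288	1	1
SYN_P00115	109	0.8976334546793225	1	1
SYN_P00116	206	8.41105093461553	1	1
SYN_P00117	193	5.085483328434551	1	1
SYN_P00118	965	0.6827456102182029	1	1
SYN_P00119	127	0.0045172150377267035	1	9.087551155222563
SYN_P00120	268	1.1296787243924689	1	1
SYN_P00121	118	3.150317983756994	1	1
SYN_P00122	120	1.095934210107787	1	1
SYN_P00123	266	1.3700196466419239	1	1
SYN_P00124	152	2.370570742411433	1	1
SYN_P00125	250	0.4524402937325281	1	1
SYN_P00126	202	13.735125427986457	1	1
SYN_P00127	184	2.561996403654831	1	1
SYN_P00128	91	0.08329718356300343	1	1
SYN_P00129	136	15.849705390035307	1	1
SYN_P00130	273	11.121919313010737	1	1
SYN_P00131	332	5.1973450472347125	1	1
SYN_P00132	195	0.03596321011294397	1	1
SYN_P00133	250	0.3202630187455454	1	1
SYN_P00134	438	3.564513698412321	1	1
SYN_P00135	514	1.091381161928155	1	28.30753483112941
SYN_P00136	144	2.0057631410571277	4.515421716324546	0.19188804747257793
SYN_P00137	236	97.06903118449259	1	1
SYN_P00138	456	0.19460943062835617	1	1
SYN_P00139	198	0.01460487021009186	1	1
SYN_P00140	244	1.728736067824778	1	1
SYN_P00141	239	0.2527906299451313	1	1
SYN_P00142	160	2.4402051311716555	1	1
SYN_P00143	200	0.19695707890096834	1	1
SYN_P00144	246	83.438594045989	1	1
SYN_P00145	203	0.7808189742392736	1	1
SYN_P00146	436	0.3849387639346446	1	1
SYN_P00147	197	0.7171121873043947	1	1
SYN_P00148	201	5.613232558664054	1	1
SYN_P00149	354	1.214923328159215	1	1
SYN_P00150	147	0.03872641016776289	1	1
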