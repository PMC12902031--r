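ID	GeneID	geneSymbol	chr	strand	longExonStart_0base	longExonEnd	shortES	shortEE	flankingES	flankingEE	ID.1	IJC_SAMPLE_1	SJC_SAMPLE_1	IJC_SAMPLE_2	SJC_SAMPLE_2	IncFormLen	SkipFormLen	PValue	FDR	IncLevel1	IncLevel2	IncLevelDifference
A3SS:chr_g0001:+:579-906-911	g0001	g0001	chr_g0001	+	906	966	911	971	519	579	A3SS:chr_g0001:+:579-906-911	46,46,46	34,34,34	85,85,85	6,6,6	1	1	9.72672381e-21	2.701867725e-20	0.575,0.575,0.575	0.934066,0.934066,0.934066	-0.3082353432
A3SS:chr_g0002:-:540-545-749	g0002	g0002	chr_g0002	-	485	545	480	540	749	809	A3SS:chr_g0002:-:540-545-749	55,55,55	45,45,45	98,98,98	12,12,12	1	1	1.040411187e-19	2.601027968e-19	0.55,0.55,0.55	0.890909,0.890909,0.890909	-0.3022753089
A3SS:chr_g0003:+:598-878-883	g0003	g0003	chr_g0003	+	878	938	883	943	538	598	A3SS:chr_g0003:+:598-878-883	57,57,57	53,53,53	89,89,89	12,12,12	1	1	4.715136934e-22	1.964640389e-21	0.518182,0.518182,0.518182	0.881188,0.881188,0.881188	-0.3677102862
A3SS:chr_g0005:+:641-847-852	g0005	g0005	chr_g0005	+	847	907	852	912	581	641	A3SS:chr_g0005:+:641-847-852	39,39,39	37,37,37	83,83,83	14,14,14	1	1	1.584793177e-24	1.320660981e-23	0.513158,0.513158,0.513158	0.85567,0.85567,0.85567	-0.3453357563
A3SS:chr_g0006:-:617-621-967	g0006	g0006	chr_g0006	-	561	621	557	617	967	1027	A3SS:chr_g0006:-:617-621-967	53,53,53	48,48,48	124,124,124	30,30,30	1	1	1.471014391e-14	2.163256457e-14	0.524752,0.524752,0.524752	0.805195,0.805195,0.805195	-0.2749129503
A3SS:chr_g0007:+:507-852-861	g0007	g0007	chr_g0007	+	852	912	861	921	447	507	A3SS:chr_g0007:+:507-852-861	70,70,70	41,41,41	76,76,76	8,8,8	1	1	8.089794584e-13	1.123582581e-12	0.630631,0.630631,0.630631	0.904762,0.904762,0.904762	-0.2576687725
A3SS:chr_g0009:+:685-837-847	g0009	g0009	chr_g0009	+	837	897	847	907	625	685	A3SS:chr_g0009:+:685-837-847	32,32,32	46,46,46	12,12,12	72,72,72	1	1	2.254490542e-09	2.818113178e-09	0.410256,0.410256,0.410256	0.142857,0.142857,0.142857	0.2253478476
A3SS:chr_g0010:-:460-477-861	g0010	g0010	chr_g0010	-	417	477	400	460	861	921	A3SS:chr_g0010:-:460-477-861	86,86,86	31,31,31	115,115,115	8,8,8	1	1	5.10000904e-17	9.107159001e-17	0.735043,0.735043,0.735043	0.934959,0.934959,0.934959	-0.2521556622
A3SS:chr_g0011:+:619-969-984	g0011	g0011	chr_g0011	+	969	1029	984	1044	559	619	A3SS:chr_g0011:+:619-969-984	69,69,69	54,54,54	101,101,101	17,17,17	1	1	1.297559736e-15	2.16259956e-15	0.560976,0.560976,0.560976	0.855932,0.855932,0.855932	-0.2791045409
A3SS:chr_g0012:-:628-637-829	g0012	g0012	chr_g0012	-	577	637	568	628	829	889	A3SS:chr_g0012:-:628-637-829	41,41,41	44,44,44	100,100,100	15,15,15	1	1	1.050440308e-21	3.282625962e-21	0.482353,0.482353,0.482353	0.869565,0.869565,0.869565	-0.3484005142
A3SS:chr_g0013:+:751-1151-1155	g0013	g0013	chr_g0013	+	1151	1211	1155	1215	691	751	A3SS:chr_g0013:+:751-1151-1155	42,42,42	34,34,34	118,118,118	20,20,20	1	1	5.374517413e-19	1.22148123e-18	0.552632,0.552632,0.552632	0.855072,0.855072,0.855072	-0.3193647448
A3SS:chr_g0014:-:497-503-893	g0014	g0014	chr_g0014	-	443	503	437	497	893	953	A3SS:chr_g0014:-:497-503-893	74,74,74	54,54,54	95,95,95	2,2,2	1	1	1.450984701e-25	3.627461753e-24	0.578125,0.578125,0.578125	0.979381,0.979381,0.979381	-0.322321273
A3SS:chr_g0015:+:608-771-780	g0015	g0015	chr_g0015	+	771	831	780	840	548	608	A3SS:chr_g0015:+:608-771-780	42,42,42	29,29,29	87,87,87	9,9,9	1	1	7.601663822e-22	2.714879936e-21	0.591549,0.591549,0.591549	0.90625,0.90625,0.90625	-0.3502488688
A3SS:chr_g0016:-:587-593-866	g0016	g0016	chr_g0016	-	533	593	527	587	866	926	A3SS:chr_g0016:-:587-593-866	56,56,56	27,27,27	89,89,89	12,12,12	1	1	1.330836501e-12	1.751100659e-12	0.674699,0.674699,0.674699	0.881188,0.881188,0.881188	-0.2640265003
A3SS:chr_g0019:+:581-927-936	g0019	g0019	chr_g0019	+	927	987	936	996	521	581	A3SS:chr_g0019:+:581-927-936	64,64,64	31,31,31	89,89,89	12,12,12	1	1	9.861379137e-23	4.930689568e-22	0.673684,0.673684,0.673684	0.881188,0.881188,0.881188	-0.325844249
A3SS:chr_g0020:-:494-502-858	g0020	g0020	chr_g0020	-	442	502	434	494	858	918	A3SS:chr_g0020:-:494-502-858	25,25,25	21,21,21	64,64,64	7,7,7	1	1	1.044795115e-14	1.632492367e-14	0.543478,0.543478,0.543478	0.901408,0.901408,0.901408	-0.3153900831
A3SS:chr_g0021:+:687-1001-1006	g0021	g0021	chr_g0021	+	1001	1061	1006	1066	627	687	A3SS:chr_g0021:+:687-1001-1006	49,49,49	48,48,48	97,97,97	20,20,20	1	1	1.829802127e-17	3.518850244e-17	0.505155,0.505155,0.505155	0.82906,0.82906,0.82906	-0.2966925573
A3SS:chr_g0023:+:522-772-781	g0023	g0023	chr_g0023	+	772	832	781	841	462	522	A3SS:chr_g0023:+:522-772-781	46,46,46	41,41,41	85,85,85	11,11,11	1	1	6.594460597e-19	1.373845958e-18	0.528736,0.528736,0.528736	0.885417,0.885417,0.885417	-0.3458929945
A3SS:chr_g0024:-:530-542-935	g0024	g0024	chr_g0024	-	482	542	470	530	935	995	A3SS:chr_g0024:-:530-542-935	57,57,57	72,72,72	100,100,100	21,21,21	1	1	1.487126322e-24	1.320660981e-23	0.44186,0.44186,0.44186	0.826446,0.826446,0.826446	-0.3698800855
A3SS:chr_g0025:+:557-812-821	g0025	g0025	chr_g0025	+	812	872	821	881	497	557	A3SS:chr_g0025:+:557-812-821	38,38,38	30,30,30	68,68,68	2,2,2	1	1	1.012504272e-23	6.328151699e-23	0.558824,0.558824,0.558824	0.971429,0.971429,0.971429	-0.3422726767
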