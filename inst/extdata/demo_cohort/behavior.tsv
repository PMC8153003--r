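mouse_id	group	asr_baseline	asr1_pct	asr2_pct	of_measure	epm_measure	sm_measure	latent_susceptibility
M01	control	219.435	69.3447	98.944	70.7532	56.3498	19.0608	NA
M02	control	236.633	127.113	69.9496	98.78	31.4654	72.8759	NA
M03	control	182.435	96.2222	97.5463	86.5505	29.0094	66.2528	NA
M04	control	169.105	87.7415	108.597	116.515	31.6761	34.5354	NA
M05	control	290.463	112.425	99.3479	154.774	45.7077	78.7904	NA
M06	control	316.409	78.6074	106.188	109.266	39.0737	84.9349	NA
M07	control	329.103	105.671	121.645	79.9277	32.7482	86.8085	NA
M08	control	232.785	105.616	94.5512	101.153	25.7797	49.704	NA
M09	control	241.577	125.557	105.181	97.5146	30.8339	74.521	NA
M10	control	237.846	112.149	102.204	35.2373	43.9219	61.1212	NA
M11	control	202.271	121.268	97.9862	125.894	45.3326	50.0227	NA
M12	control	264.463	91.9729	106.147	106.323	44.5926	84.6733	NA
M13	control	263.976	107.014	101.85	138.364	34.1315	85.9226	NA
M14	control	220.608	69.5728	91.6796	150.418	47.1426	40.6061	NA
M15	control	270.537	88.6653	86.3664	94.0856	32.6949	82.5024	NA
M16	control	246.024	104.421	101.958	111.508	44.9783	36.3004	NA
M17	control	231.297	85.7204	122.028	143.928	33.3751	47.7188	NA
M18	control	269.734	85.8166	75.3185	83.0366	31.5712	51.863	NA
M19	stressed	226.227	114.589	121.011	112.461	38.6691	33.7371	0.333486
M20	stressed	182.853	110.686	117.489	95.3694	22.979	28.7685	0.16149
M21	stressed	181.313	133.618	90.1512	128.862	36.5985	36.0814	0.394379
M22	stressed	330.43	99.5063	99.5039	81.6821	20.0185	60.9434	0.508929
M23	stressed	234.242	97.8899	86.3817	112.281	22.0615	38.391	-0.953345
M24	stressed	238.235	129.657	115.499	103.699	20.8805	35.3365	1.184
M25	stressed	255.917	101.403	92.8973	70.1248	39.6275	74.3773	-1.2799
M26	stressed	227.81	125.191	107.427	123.028	25.9172	40.0715	0.370472
M27	stressed	211.268	101.1	91.7659	116.005	17.7473	50.8428	-1.45103
M28	stressed	261.042	85.9538	101.691	118.766	22.7864	53.4503	-1.44337
M29	stressed	146.778	121.977	147.394	57.683	34.6224	39.7364	1.62231
M30	stressed	280.493	107.74	101.238	89.264	17.0554	49.9121	-0.024783
M31	stressed	163.99	139.817	153.429	46.3505	10.647	35.3332	1.74035
M32	stressed	256.263	103.006	117.312	148.495	32.7779	36.2681	0.216696
M33	stressed	253.991	93.4654	112.675	105.429	23.7767	36.6394	-0.77672
M34	stressed	226.582	98.2578	100.087	110.221	24.759	54.6075	-0.442539
M35	stressed	260.709	113.657	116.318	105.849	34.852	17.2193	1.11906
M36	stressed	182.834	99.7876	110.58	59.4875	25.9967	64.8131	-0.138897
M37	stressed	175.198	97.9908	97.126	104.663	15.9124	57.077	0.685953
M38	stressed	270.873	108.205	115.071	126.662	41.5657	47.0117	0.168494
M39	stressed	213.585	105.636	89.1277	108.315	36.0128	63.7382	-0.317873
M40	stressed	179.29	66.6816	101.092	148.078	27.4823	78.7769	-2.13141
M41	stressed	231.935	95.698	94.1227	85.988	26.452	49.4656	-0.81288
M42	stressed	277.301	117.607	123.019	107.303	14.991	11.4778	1.54482
M43	stressed	228.305	112.65	107.232	125.015	13.027	62.2991	1.23581
M44	stressed	235.144	114.683	109.811	80.7332	21.4683	32.6117	0.470778
M45	stressed	341.593	110.59	100.004	92.6731	22.1486	58.7499	-0.562967
M46	stressed	259.413	116.397	101.817	89.4094	-4.5514	22.8258	-0.108813
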