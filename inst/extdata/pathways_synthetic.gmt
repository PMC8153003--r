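NEUROTROPHIN_SIGNALING_SYN	synthetic_fixture	GENE020	GENE030	GENE031	GENE060	GENE061	GENE081	GENE083	GENE108	GENE110	GENE152	GENE176	GENE201	GENE202	GENE207	GENE226	GENE230	GENE231	GENE238	GENE253	GENE257	GENE271	GENE272	GENE285	GENE289	GENE294	GENE301	GENE317	GENE322	GENE364	GENE377	GENE390
MAPK_CASCADE_SYN	synthetic_fixture	GENE073	GENE082	GENE086	GENE093	GENE127	GENE140	GENE162	GENE175	GENE195	GENE233	GENE239	GENE304	GENE329	GENE354	GENE360	GENE386
GLUCOCORTICOID_RESPONSE_SYN	synthetic_fixture	GENE016	GENE025	GENE036	GENE037	GENE049	GENE057	GENE131	GENE132	GENE168	GENE185	GENE186	GENE244	GENE249	GENE268	GENE306	GENE319	GENE323	GENE350	GENE351	GENE369
RANDOM_PATHWAY_SYN_01	synthetic_fixture	GENE010	GENE019	GENE031	GENE045	GENE050	GENE060	GENE075	GENE083	GENE100	GENE107	GENE157	GENE178	GENE193	GENE194	GENE201	GENE226	GENE230	GENE233	GENE239	GENE245	GENE249	GENE257	GENE262	GENE270	GENE300	GENE324	GENE359	GENE373	GENE399
RANDOM_PATHWAY_SYN_02	synthetic_fixture	GENE001	GENE015	GENE019	GENE021	GENE062	GENE071	GENE072	GENE122	GENE124	GENE129	GENE141	GENE149	GENE160	GENE167	GENE175	GENE215	GENE237	GENE244	GENE247	GENE248	GENE255	GENE259	GENE272	GENE303	GENE310	GENE318	GENE319	GENE323	GENE349	GENE354	GENE357	GENE358	GENE365	GENE369	GENE372	GENE375	GENE378	GENE395
RANDOM_PATHWAY_SYN_03	synthetic_fixture	GENE019	GENE022	GENE049	GENE073	GENE109	GENE151	GENE190	GENE237	GENE259	GENE266	GENE268	GENE270	GENE276	GENE326	GENE333	GENE348	GENE359	GENE360	GENE368	GENE375	GENE383
RANDOM_PATHWAY_SYN_04	synthetic_fixture	GENE009	GENE020	GENE030	GENE033	GENE068	GENE071	GENE077	GENE080	GENE085	GENE098	GENE100	GENE132	GENE136	GENE146	GENE151	GENE176	GENE182	GENE205	GENE209	GENE225	GENE238	GENE245	GENE247	GENE264	GENE281	GENE284	GENE315	GENE351	GENE353	GENE359	GENE372	GENE378	GENE379	GENE383	GENE390
RANDOM_PATHWAY_SYN_05	synthetic_fixture	GENE002	GENE012	GENE022	GENE062	GENE085	GENE094	GENE097	GENE104	GENE116	GENE127	GENE145	GENE157	GENE182	GENE197	GENE201	GENE222	GENE231	GENE232	GENE244	GENE266	GENE303	GENE335	GENE342	GENE359	GENE370
RANDOM_PATHWAY_SYN_06	synthetic_fixture	GENE005	GENE009	GENE014	GENE019	GENE042	GENE057	GENE071	GENE074	GENE083	GENE095	GENE105	GENE109	GENE117	GENE118	GENE119	GENE129	GENE149	GENE155	GENE163	GENE167	GENE192	GENE206	GENE209	GENE224	GENE228	GENE250	GENE257	GENE261	GENE271	GENE273	GENE274	GENE290	GENE302	GENE319	GENE320	GENE321	GENE346	GENE348	GENE374
RANDOM_PATHWAY_SYN_07	synthetic_fixture	GENE034	GENE039	GENE052	GENE062	GENE080	GENE087	GENE088	GENE089	GENE130	GENE138	GENE139	GENE147	GENE178	GENE182	GENE196	GENE202	GENE203	GENE206	GENE209	GENE211	GENE212	GENE218	GENE230	GENE240	GENE284	GENE294	GENE297	GENE306	GENE307	GENE316	GENE346	GENE358	GENE359	GENE362	GENE376	GENE377	GENE382	GENE389
RANDOM_PATHWAY_SYN_08	synthetic_fixture	GENE019	GENE027	GENE028	GENE041	GENE075	GENE089	GENE102	GENE124	GENE125	GENE164	GENE167	GENE172	GENE193	GENE220	GENE292	GENE307	GENE328	GENE330	GENE333	GENE361	GENE372	GENE391	GENE393	GENE394
RANDOM_PATHWAY_SYN_09	synthetic_fixture	GENE006	GENE018	GENE021	GENE027	GENE034	GENE050	GENE088	GENE090	GENE097	GENE100	GENE114	GENE120	GENE161	GENE165	GENE170	GENE171	GENE180	GENE195	GENE220	GENE230	GENE242	GENE293	GENE308	GENE316	GENE319	GENE320	GENE329	GENE335	GENE374	GENE379
RANDOM_PATHWAY_SYN_10	synthetic_fixture	GENE022	GENE024	GENE044	GENE054	GENE132	GENE176	GENE191	GENE207	GENE213	GENE232	GENE256	GENE264	GENE280	GENE286	GENE289	GENE342	GENE357	GENE396	GENE399
RANDOM_PATHWAY_SYN_11	synthetic_fixture	GENE139	GENE184	GENE196	GENE208	GENE212	GENE254	GENE261	GENE265	GENE277	GENE308	GENE321	GENE329	GENE334	GENE352	GENE373	GENE376	GENE379	GENE397
RANDOM_PATHWAY_SYN_12	synthetic_fixture	GENE018	GENE020	GENE034	GENE043	GENE046	GENE047	GENE052	GENE056	GENE067	GENE086	GENE091	GENE106	GENE111	GENE115	GENE131	GENE139	GENE156	GENE164	GENE166	GENE171	GENE184	GENE190	GENE206	GENE219	GENE229	GENE230	GENE232	GENE235	GENE236	GENE248	GENE250	GENE253	GENE294	GENE308	GENE337	GENE366	GENE392	GENE395
RANDOM_PATHWAY_SYN_13	synthetic_fixture	GENE009	GENE019	GENE032	GENE056	GENE065	GENE109	GENE144	GENE156	GENE164	GENE175	GENE178	GENE187	GENE193	GENE210	GENE230	GENE241	GENE247	GENE248	GENE268	GENE275	GENE287	GENE293	GENE306	GENE308	GENE312	GENE314	GENE316	GENE341	GENE344	GENE346	GENE360	GENE363
RANDOM_PATHWAY_SYN_14	synthetic_fixture	GENE017	GENE033	GENE034	GENE040	GENE042	GENE056	GENE057	GENE084	GENE101	GENE106	GENE165	GENE179	GENE189	GENE214	GENE225	GENE251	GENE273	GENE282	GENE301	GENE316	GENE347
RANDOM_PATHWAY_SYN_15	synthetic_fixture	GENE002	GENE022	GENE034	GENE068	GENE085	GENE110	GENE123	GENE136	GENE138	GENE144	GENE154	GENE156	GENE162	GENE165	GENE172	GENE187	GENE189	GENE199	GENE206	GENE210	GENE217	GENE220	GENE221	GENE224	GENE228	GENE246	GENE258	GENE268	GENE277	GENE279	GENE307	GENE310	GENE314	GENE360	GENE362	GENE369	GENE385	GENE386	GENE389
RANDOM_PATHWAY_SYN_16	synthetic_fixture	GENE001	GENE034	GENE067	GENE077	GENE093	GENE098	GENE118	GENE128	GENE150	GENE156	GENE171	GENE208	GENE213	GENE246	GENE253	GENE256	GENE259	GENE265	GENE282	GENE313	GENE322	GENE323	GENE324	GENE325	GENE337	GENE339	GENE350	GENE352	GENE366	GENE387	GENE389
RANDOM_PATHWAY_SYN_17	synthetic_fixture	GENE018	GENE020	GENE025	GENE026	GENE039	GENE041	GENE054	GENE071	GENE105	GENE108	GENE132	GENE135	GENE153	GENE157	GENE178	GENE187	GENE279	GENE303	GENE307	GENE315	GENE338	GENE352	GENE361
RANDOM_PATHWAY_SYN_18	synthetic_fixture	GENE026	GENE036	GENE045	GENE050	GENE071	GENE078	GENE092	GENE094	GENE124	GENE125	GENE140	GENE154	GENE156	GENE163	GENE165	GENE187	GENE191	GENE193	GENE199	GENE239	GENE253	GENE263	GENE268	GENE278	GENE284	GENE290	GENE294	GENE307	GENE311	GENE317	GENE334	GENE337	GENE349	GENE359	GENE363	GENE372	GENE379	GENE385	GENE393
RANDOM_PATHWAY_SYN_19	synthetic_fixture	GENE016	GENE042	GENE044	GENE055	GENE058	GENE059	GENE065	GENE070	GENE071	GENE075	GENE088	GENE089	GENE099	GENE105	GENE120	GENE131	GENE136	GENE198	GENE199	GENE226	GENE229	GENE236	GENE247	GENE257	GENE272	GENE279	GENE294	GENE295	GENE315	GENE318	GENE344	GENE357	GENE394
RANDOM_PATHWAY_SYN_20	synthetic_fixture	GENE024	GENE033	GENE046	GENE070	GENE101	GENE104	GENE121	GENE125	GENE144	GENE150	GENE219	GENE224	GENE272	GENE302	GENE337	GENE342	GENE361	GENE380	GENE385	GENE396
RANDOM_PATHWAY_SYN_21	synthetic_fixture	GENE012	GENE048	GENE121	GENE130	GENE140	GENE141	GENE142	GENE155	GENE183	GENE189	GENE199	GENE200	GENE209	GENE230	GENE233	GENE242	GENE288	GENE313	GENE353	GENE379	GENE388	GENE400
RANDOM_PATHWAY_SYN_22	synthetic_fixture	GENE002	GENE005	GENE025	GENE038	GENE056	GENE072	GENE092	GENE093	GENE097	GENE104	GENE132	GENE139	GENE142	GENE159	GENE182	GENE187	GENE192	GENE210	GENE212	GENE232	GENE236	GENE249	GENE265	GENE271	GENE344	GENE359	GENE377
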