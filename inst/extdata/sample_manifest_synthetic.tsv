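id	missing_frac	duplicate_of
S001	0.083	
S002	0.204	
S003	0.031	
S004	0.046	
S005	0.154	S233
S006	0.09	
S007	0.197	
S008	0.107	
S009	0.283	
S010	0.114	
S011	0.246	
S012	0.116	
S013	0.272	
S014	0.059	
S015	0.277	
S016	0.023	
S017	0.226	
S018	0.119	
S019	0.044	
S020	0.255	
S021	0.214	
S022	0.28	
S023	0.225	
S024	0.2	
S025	0.228	
S026	0.099	
S027	0.129	
S028	0.251	
S029	0.257	
S030	0.086	
S031	0.54	
S032	0.088	
S033	0.084	
S034	0.025	S032
S035	0.132	
S036	0.05	
S037	0.112	
S038	0.143	
S039	0.164	
S040	0.276	
S041	0.106	
S042	0.575	
S043	0.321	
S044	0.158	S007
S045	0.21	
S046	0.124	
S047	0.207	
S048	0.26	
S049	0.144	
S050	0.136	
S051	0.322	
S052	0.131	
S053	0.242	
S054	0.235	
S055	0.198	
S056	0.1	
S057	0.07	
S058	0.247	
S059	0.051	
S060	0.191	
S061	0.184	
S062	0.087	
S063	0.64	
S064	0.184	
S065	0.072	
S066	0.327	
S067	0.636	
S068	0.089	
S069	0.094	
S070	0.055	
S071	0.279	
S072	0.043	
S073	0.044	
S074	0.217	
S075	0.565	
S076	0.31	
S077	0.159	
S078	0.245	
S079	0.578	
S080	0.076	
S081	0.262	
S082	0.15	
S083	0.032	
S084	0.291	
S085	0.065	
S086	0.144	
S087	0.299	
S088	0.028	
S089	0.085	
S090	0.032	
S091	0.04	
S092	0.111	
S093	0.204	
S094	0.282	
S095	0.233	
S096	0.155	
S097	0.188	
S098	0.568	
S099	0.087	
S100	0.051	
S101	0.068	
S102	0.311	
S103	0.221	
S104	0.031	
S105	0.214	
S106	0.185	
S107	0.294	
S108	0.027	
S109	0.113	
S110	0.079	
S111	0.277	
S112	0.047	
S113	0.265	
S114	0.224	
S115	0.123	
S116	0.323	
S117	0.043	
S118	0.255	
S119	0.053	
S120	0.185	
S121	0.18	
S122	0.072	
S123	0.288	
S124	0.281	
S125	0.14	
S126	0.102	
S127	0.267	
S128	0.236	
S129	0.174	
S130	0.077	
S131	0.207	
S132	0.242	
S133	0.248	
S134	0.282	
S135	0.243	
S136	0.293	
S137	0.209	
S138	0.316	
S139	0.15	
S140	0.324	
S141	0.107	
S142	0.221	
S143	0.1	
S144	0.043	
S145	0.293	
S146	0.287	
S147	0.297	
S148	0.16	
S149	0.645	
S150	0.294	
S151	0.028	
S152	0.058	
S153	0.267	
S154	0.245	
S155	0.174	
S156	0.13	
S157	0.185	
S158	0.591	
S159	0.136	
S160	0.023	
S161	0.26	
S162	0.517	
S163	0.049	
S164	0.261	
S165	0.284	
S166	0.164	
S167	0.127	
S168	0.301	
S169	0.244	
S170	0.181	
S171	0.089	
S172	0.274	
S173	0.136	
S174	0.225	
S175	0.528	
S176	0.202	
S177	0.133	
S178	0.098	
S179	0.549	
S180	0.162	
S181	0.494	
S182	0.226	
S183	0.304	
S184	0.122	
S185	0.677	
S186	0.12	
S187	0.322	
S188	0.325	
S189	0.214	S074
S190	0.618	
S191	0.249	
S192	0.247	
S193	0.097	
S194	0.167	
S195	0.577	
S196	0.272	
S197	0.631	
S198	0.213	
S199	0.177	
S200	0.076	
S201	0.183	
S202	0.293	
S203	0.274	
S204	0.144	
S205	0.246	
S206	0.205	
S207	0.046	
S208	0.177	
S209	0.164	
S210	0.225	
S211	0.148	
S212	0.194	
S213	0.169	
S214	0.109	
S215	0.477	
S216	0.301	
S217	0.11	
S218	0.312	
S219	0.202	
S220	0.289	
S221	0.473	
S222	0.118	
S223	0.078	
S224	0.049	
S225	0.524	
S226	0.122	
S227	0.077	
S228	0.225	
S229	0.049	
S230	0.132	
S231	0.053	
S232	0.19	
S233	0.325	
S234	0.057	
S235	0.042	
S236	0.3	
S237	0.145	
S238	0.322	
S239	0.109	
S240	0.085	
S241	0.086	
S242	0.239	
S243	0.232	
S244	0.207	
S245	0.114	
S246	0.26	
S247	0.266	
S248	0.237	
S249	0.31	
S250	0.08	
S251	0.268	
S252	0.052	
S253	0.07	
S254	0.163	
S255	0.045	
S256	0.031	
S257	0.049	
S258	0.263	
S259	0.172	
S260	0.537	
S261	0.242	
S262	0.689	
S263	0.645	
S264	0.432	
S265	0.305	
S266	0.257	
S267	0.099	
S268	0.102	
S269	0.204	
S270	0.211	
S271	0.329	
S272	0.179	
S273	0.256	
S274	0.03	
S275	0.187	
S276	0.32	
S277	0.094	
S278	0.309	
S279	0.187	
S280	0.409	
S281	0.139	
S282	0.177	
S283	0.273	
S284	0.231	
S285	0.034	
S286	0.118	
S287	0.298	
S288	0.078	
S289	0.262	
S290	0.309	
S291	0.267	
S292	0.625	
S293	0.27	
S294	0.315	
S295	0.116	
S296	0.29	
S297	0.223	
S298	0.053	
S299	0.028	
S300	0.204	
S301	0.079	
S302	0.483	
S303	0.15	
S304	0.092	
S305	0.271	
S306	0.092	
S307	0.065	
S308	0.314	
S309	0.107	
S310	0.12	
S311	0.168	
S312	0.067	
S313	0.259	
S314	0.287	
S315	0.24	
S316	0.308	
S317	0.484	
S318	0.144	
S319	0.104	
S320	0.287	
S321	0.264	
S322	0.27	
S323	0.118	
S324	0.043	
S325	0.163	
S326	0.111	
S327	0.041	
S328	0.055	
S329	0.112	
S330	0.108	
S331	0.286	
S332	0.069	
S333	0.309	
S334	0.317	
S335	0.258	
S336	0.29	
S337	0.208	
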