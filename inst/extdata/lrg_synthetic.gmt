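LRG_SYNTHETIC	synthetic 371-member lactylation-related gene signature (stand-in; core metabolic/acetyltransferase symbols padded with synthetic ids)	LDHA	LDHB	LDHC	LDHAL6A	LDHAL6B	PKM	PKLR	HK1	HK2	HK3	GPI	PFKL	PFKM	PFKP	ALDOA	ALDOB	ALDOC	TPI1	GAPDH	PGK1	PGK2	PGAM1	PGAM2	ENO1	ENO2	ENO3	SLC16A1	SLC16A3	SLC16A7	SLC16A8	SLC2A1	SLC2A3	MPC1	MPC2	PDHA1	PDHB	DLAT	DLD	PDK1	PDK2	PDK3	PDK4	PDP1	PDP2	EP300	CREBBP	KAT2A	KAT2B	KAT5	KAT6A	KAT6B	KAT7	KAT8	HDAC1	HDAC2	HDAC3	HDAC8	SIRT1	SIRT2	SIRT3	MYC	HIF1A	ARNT	VHL	EPAS1	GYS1	PYGL	G6PD	PGD	TKT	TALDO1	ME1	ME2	GOT1	GOT2	MDH1	MDH2	CS	ACLY	ACSS2	SSBP1	RPA3	TUBB2A	LRGS001	LRGS002	LRGS003	LRGS004	LRGS005	LRGS006	LRGS007	LRGS008	LRGS009	LRGS010	LRGS011	LRGS012	LRGS013	LRGS014	LRGS015	LRGS016	LRGS017	LRGS018	LRGS019	LRGS020	LRGS021	LRGS022	LRGS023	LRGS024	LRGS025	LRGS026	LRGS027	LRGS028	LRGS029	LRGS030	LRGS031	LRGS032	LRGS033	LRGS034	LRGS035	LRGS036	LRGS037	LRGS038	LRGS039	LRGS040	LRGS041	LRGS042	LRGS043	LRGS044	LRGS045	LRGS046	LRGS047	LRGS048	LRGS049	LRGS050	LRGS051	LRGS052	LRGS053	LRGS054	LRGS055	LRGS056	LRGS057	LRGS058	LRGS059	LRGS060	LRGS061	LRGS062	LRGS063	LRGS064	LRGS065	LRGS066	LRGS067	LRGS068	LRGS069	LRGS070	LRGS071	LRGS072	LRGS073	LRGS074	LRGS075	LRGS076	LRGS077	LRGS078	LRGS079	LRGS080	LRGS081	LRGS082	LRGS083	LRGS084	LRGS085	LRGS086	LRGS087	LRGS088	LRGS089	LRGS090	LRGS091	LRGS092	LRGS093	LRGS094	LRGS095	LRGS096	LRGS097	LRGS098	LRGS099	LRGS100	LRGS101	LRGS102	LRGS103	LRGS104	LRGS105	LRGS106	LRGS107	LRGS108	LRGS109	LRGS110	LRGS111	LRGS112	LRGS113	LRGS114	LRGS115	LRGS116	LRGS117	LRGS118	LRGS119	LRGS120	LRGS121	LRGS122	LRGS123	LRGS124	LRGS125	LRGS126	LRGS127	LRGS128	LRGS129	LRGS130	LRGS131	LRGS132	LRGS133	LRGS134	LRGS135	LRGS136	LRGS137	LRGS138	LRGS139	LRGS140	LRGS141	LRGS142	LRGS143	LRGS144	LRGS145	LRGS146	LRGS147	LRGS148	LRGS149	LRGS150	LRGS151	LRGS152	LRGS153	LRGS154	LRGS155	LRGS156	LRGS157	LRGS158	LRGS159	LRGS160	LRGS161	LRGS162	LRGS163	LRGS164	LRGS165	LRGS166	LRGS167	LRGS168	LRGS169	LRGS170	LRGS171	LRGS172	LRGS173	LRGS174	LRGS175	LRGS176	LRGS177	LRGS178	LRGS179	LRGS180	LRGS181	LRGS182	LRGS183	LRGS184	LRGS185	LRGS186	LRGS187	LRGS188	LRGS189	LRGS190	LRGS191	LRGS192	LRGS193	LRGS194	LRGS195	LRGS196	LRGS197	LRGS198	LRGS199	LRGS200	LRGS201	LRGS202	LRGS203	LRGS204	LRGS205	LRGS206	LRGS207	LRGS208	LRGS209	LRGS210	LRGS211	LRGS212	LRGS213	LRGS214	LRGS215	LRGS216	LRGS217	LRGS218	LRGS219	LRGS220	LRGS221	LRGS222	LRGS223	LRGS224	LRGS225	LRGS226	LRGS227	LRGS228	LRGS229	LRGS230	LRGS231	LRGS232	LRGS233	LRGS234	LRGS235	LRGS236	LRGS237	LRGS238	LRGS239	LRGS240	LRGS241	LRGS242	LRGS243	LRGS244	LRGS245	LRGS246	LRGS247	LRGS248	LRGS249	LRGS250	LRGS251	LRGS252	LRGS253	LRGS254	LRGS255	LRGS256	LRGS257	LRGS258	LRGS259	LRGS260	LRGS261	LRGS262	LRGS263	LRGS264	LRGS265	LRGS266	LRGS267	LRGS268	LRGS269	LRGS270	LRGS271	LRGS272	LRGS273	LRGS274	LRGS275	LRGS276	LRGS277	LRGS278	LRGS279	LRGS280	LRGS281	LRGS282	LRGS283	LRGS284	LRGS285	LRGS286	LRGS287	LRGS288
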