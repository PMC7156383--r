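OXPHOG	synthetic_standin_oxphos_plus_glycolysis	OXPHOG001	OXPHOG002	OXPHOG003	OXPHOG004	OXPHOG005	OXPHOG006	OXPHOG007	OXPHOG008	OXPHOG009	OXPHOG010	OXPHOG011	OXPHOG012	OXPHOG013	OXPHOG014	OXPHOG015	OXPHOG016	OXPHOG017	OXPHOG018	OXPHOG019	OXPHOG020	OXPHOG021	OXPHOG022	OXPHOG023	OXPHOG024	OXPHOG025	OXPHOG026	OXPHOG027	OXPHOG028	OXPHOG029	OXPHOG030	OXPHOG031	OXPHOG032	OXPHOG033	OXPHOG034	OXPHOG035	OXPHOG036	OXPHOG037	OXPHOG038	OXPHOG039	OXPHOG040	OXPHOG041	OXPHOG042	OXPHOG043	OXPHOG044	OXPHOG045	OXPHOG046	OXPHOG047	OXPHOG048	OXPHOG049	OXPHOG050	OXPHOG051	OXPHOG052	OXPHOG053	OXPHOG054	OXPHOG055	OXPHOG056	OXPHOG057	OXPHOG058	OXPHOG059	OXPHOG060	OXPHOG061	OXPHOG062	OXPHOG063	OXPHOG064	OXPHOG065	OXPHOG066	OXPHOG067	OXPHOG068	OXPHOG069	OXPHOG070	OXPHOG071	OXPHOG072	OXPHOG073	OXPHOG074	OXPHOG075	OXPHOG076	OXPHOG077	OXPHOG078	OXPHOG079	OXPHOG080	OXPHOG081	OXPHOG082	OXPHOG083	OXPHOG084	OXPHOG085	OXPHOG086	OXPHOG087	OXPHOG088	OXPHOG089	OXPHOG090	OXPHOG091	OXPHOG092	OXPHOG093	OXPHOG094	OXPHOG095	OXPHOG096	OXPHOG097	OXPHOG098	OXPHOG099	OXPHOG100	OXPHOG101	OXPHOG102	OXPHOG103	OXPHOG104	OXPHOG105	OXPHOG106	OXPHOG107	OXPHOG108	OXPHOG109	OXPHOG110	OXPHOG111	OXPHOG112	OXPHOG113	OXPHOG114	OXPHOG115	OXPHOG116	OXPHOG117	OXPHOG118
OXPHOG_CORE32	synthetic_standin_core_upregulated_panel	OXPHOG001	OXPHOG002	OXPHOG003	OXPHOG004	OXPHOG005	OXPHOG006	OXPHOG007	OXPHOG008	OXPHOG009	OXPHOG010	OXPHOG011	OXPHOG012	OXPHOG013	OXPHOG014	OXPHOG015	OXPHOG016	OXPHOG017	OXPHOG018	OXPHOG019	OXPHOG020	OXPHOG021	OXPHOG022	OXPHOG023	OXPHOG024	OXPHOG025	OXPHOG026	OXPHOG027	OXPHOG028	OXPHOG029	OXPHOG030	OXPHOG031	OXPHOG032
MUSCLE28	synthetic_standin_skeletal_muscle_panel	MUSC01	MUSC02	MUSC03	MUSC04	MUSC05	MUSC06	MUSC07	MUSC08	MUSC09	MUSC10	MUSC11	MUSC12	MUSC13	MUSC14	MUSC15	MUSC16	MUSC17	MUSC18	MUSC19	MUSC20	MUSC21	MUSC22	MUSC23	MUSC24	MUSC25	MUSC26	MUSC27	MUSC28
HYPOXIA200	synthetic_standin_hallmark_hypoxia	HYPX001	HYPX002	HYPX003	HYPX004	HYPX005	HYPX006	HYPX007	HYPX008	HYPX009	HYPX010	HYPX011	HYPX012	HYPX013	HYPX014	HYPX015	HYPX016	HYPX017	HYPX018	HYPX019	HYPX020	HYPX021	HYPX022	HYPX023	HYPX024	HYPX025	HYPX026	HYPX027	HYPX028	HYPX029	HYPX030	HYPX031	HYPX032	HYPX033	HYPX034	HYPX035	HYPX036	HYPX037	HYPX038	HYPX039	HYPX040	HYPX041	HYPX042	HYPX043	HYPX044	HYPX045	HYPX046	HYPX047	HYPX048	HYPX049	HYPX050	HYPX051	HYPX052	HYPX053	HYPX054	HYPX055	HYPX056	HYPX057	HYPX058	HYPX059	HYPX060	HYPX061	HYPX062	HYPX063	HYPX064	HYPX065	HYPX066	HYPX067	HYPX068	HYPX069	HYPX070	HYPX071	HYPX072	HYPX073	HYPX074	HYPX075	HYPX076	HYPX077	HYPX078	HYPX079	HYPX080	HYPX081	HYPX082	HYPX083	HYPX084	HYPX085	HYPX086	HYPX087	HYPX088	HYPX089	HYPX090	HYPX091	HYPX092	HYPX093	HYPX094	HYPX095	HYPX096	HYPX097	HYPX098	HYPX099	HYPX100	HYPX101	HYPX102	HYPX103	HYPX104	HYPX105	HYPX106	HYPX107	HYPX108	HYPX109	HYPX110	HYPX111	HYPX112	HYPX113	HYPX114	HYPX115	HYPX116	HYPX117	HYPX118	HYPX119	HYPX120	HYPX121	HYPX122	HYPX123	HYPX124	HYPX125	HYPX126	HYPX127	HYPX128	HYPX129	HYPX130	HYPX131	HYPX132	HYPX133	HYPX134	HYPX135	HYPX136	HYPX137	HYPX138	HYPX139	HYPX140	HYPX141	HYPX142	HYPX143	HYPX144	HYPX145	HYPX146	HYPX147	HYPX148	HYPX149	HYPX150	HYPX151	HYPX152	HYPX153	HYPX154	HYPX155	HYPX156	HYPX157	HYPX158	HYPX159	HYPX160	HYPX161	HYPX162	HYPX163	HYPX164	HYPX165	HYPX166	HYPX167	HYPX168	HYPX169	HYPX170	HYPX171	HYPX172	HYPX173	HYPX174	HYPX175	HYPX176	HYPX177	HYPX178	HYPX179	HYPX180	HYPX181	HYPX182	HYPX183	HYPX184	HYPX185	HYPX186	HYPX187	HYPX188	HYPX189	HYPX190	HYPX191	HYPX192	HYPX193	HYPX194	HYPX195	HYPX196	HYPX197	HYPX198	HYPX199	HYPX200
IMMUNE_CYTOTOXIC	synthetic_standin_immune_subset	CYTOTOXIC01	CYTOTOXIC02	CYTOTOXIC03	CYTOTOXIC04	CYTOTOXIC05	CYTOTOXIC06	CYTOTOXIC07	CYTOTOXIC08	CYTOTOXIC09	CYTOTOXIC10	CYTOTOXIC11	CYTOTOXIC12	CYTOTOXIC13	CYTOTOXIC14	CYTOTOXIC15
IMMUNE_CD8	synthetic_standin_immune_subset	CD801	CD802	CD803	CD804	CD805	CD806	CD807	CD808	CD809	CD810	CD811	CD812	CD813	CD814	CD815
IMMUNE_TREG	synthetic_standin_immune_subset	TREG01	TREG02	TREG03	TREG04	TREG05	TREG06	TREG07	TREG08	TREG09	TREG10	TREG11	TREG12	TREG13	TREG14	TREG15
IMMUNE_TH1	synthetic_standin_immune_subset	TH101	TH102	TH103	TH104	TH105	TH106	TH107	TH108	TH109	TH110	TH111	TH112	TH113	TH114	TH115
IMMUNE_TH2	synthetic_standin_immune_subset	TH201	TH202	TH203	TH204	TH205	TH206	TH207	TH208	TH209	TH210	TH211	TH212	TH213	TH214	TH215
IMMUNE_TH17	synthetic_standin_immune_subset	TH1701	TH1702	TH1703	TH1704	TH1705	TH1706	TH1707	TH1708	TH1709	TH1710	TH1711	TH1712	TH1713	TH1714	TH1715
IMMUNE_NK	synthetic_standin_immune_subset	NK01	NK02	NK03	NK04	NK05	NK06	NK07	NK08	NK09	NK10	NK11	NK12	NK13	NK14	NK15
IMMUNE_NK56DIM	synthetic_standin_immune_subset	NK56DIM01	NK56DIM02	NK56DIM03	NK56DIM04	NK56DIM05	NK56DIM06	NK56DIM07	NK56DIM08	NK56DIM09	NK56DIM10	NK56DIM11	NK56DIM12	NK56DIM13	NK56DIM14	NK56DIM15
IMMUNE_BCELL	synthetic_standin_immune_subset	BCELL01	BCELL02	BCELL03	BCELL04	BCELL05	BCELL06	BCELL07	BCELL08	BCELL09	BCELL10	BCELL11	BCELL12	BCELL13	BCELL14	BCELL15
IMMUNE_MACROPHAGE	synthetic_standin_immune_subset	MACROPHAGE01	MACROPHAGE02	MACROPHAGE03	MACROPHAGE04	MACROPHAGE05	MACROPHAGE06	MACROPHAGE07	MACROPHAGE08	MACROPHAGE09	MACROPHAGE10	MACROPHAGE11	MACROPHAGE12	MACROPHAGE13	MACROPHAGE14	MACROPHAGE15
IMMUNE_DENDRITIC	synthetic_standin_immune_subset	DENDRITIC01	DENDRITIC02	DENDRITIC03	DENDRITIC04	DENDRITIC05	DENDRITIC06	DENDRITIC07	DENDRITIC08	DENDRITIC09	DENDRITIC10	DENDRITIC11	DENDRITIC12	DENDRITIC13	DENDRITIC14	DENDRITIC15
IMMUNE_MAST	synthetic_standin_immune_subset	MAST01	MAST02	MAST03	MAST04	MAST05	MAST06	MAST07	MAST08	MAST09	MAST10	MAST11	MAST12	MAST13	MAST14	MAST15
IMMUNE_NEUTROPHIL	synthetic_standin_immune_subset	NEUTROPHIL01	NEUTROPHIL02	NEUTROPHIL03	NEUTROPHIL04	NEUTROPHIL05	NEUTROPHIL06	NEUTROPHIL07	NEUTROPHIL08	NEUTROPHIL09	NEUTROPHIL10	NEUTROPHIL11	NEUTROPHIL12	NEUTROPHIL13	NEUTROPHIL14	NEUTROPHIL15
IMMUNE_EOSINOPHIL	synthetic_standin_immune_subset	EOSINOPHIL01	EOSINOPHIL02	EOSINOPHIL03	EOSINOPHIL04	EOSINOPHIL05	EOSINOPHIL06	EOSINOPHIL07	EOSINOPHIL08	EOSINOPHIL09	EOSINOPHIL10	EOSINOPHIL11	EOSINOPHIL12	EOSINOPHIL13	EOSINOPHIL14	EOSINOPHIL15
IMMUNE_TFH	synthetic_standin_immune_subset	TFH01	TFH02	TFH03	TFH04	TFH05	TFH06	TFH07	TFH08	TFH09	TFH10	TFH11	TFH12	TFH13	TFH14	TFH15
IMMUNE_TCM	synthetic_standin_immune_subset	TCM01	TCM02	TCM03	TCM04	TCM05	TCM06	TCM07	TCM08	TCM09	TCM10	TCM11	TCM12	TCM13	TCM14	TCM15
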