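DRUG_INTERACTORS_160_SYNTHETIC	synthetic stand-in: 160-gene flavonoid-interactor list (sizes and the single shared gene are real; other symbols are placeholders)	C1QTNF2	API001	API002	API003	API004	API005	API006	API007	API008	API009	API010	API011	API012	API013	API014	API015	API016	API017	API018	API019	API020	API021	API022	API023	API024	API025	API026	API027	API028	API029	API030	API031	API032	API033	API034	API035	API036	API037	API038	API039	API040	API041	API042	API043	API044	API045	API046	API047	API048	API049	API050	API051	API052	API053	API054	API055	API056	API057	API058	API059	API060	API061	API062	API063	API064	API065	API066	API067	API068	API069	API070	API071	API072	API073	API074	API075	API076	API077	API078	API079	API080	API081	API082	API083	API084	API085	API086	API087	API088	API089	API090	API091	API092	API093	API094	API095	API096	API097	API098	API099	API100	API101	API102	API103	API104	API105	API106	API107	API108	API109	API110	API111	API112	API113	API114	API115	API116	API117	API118	API119	API120	API121	API122	API123	API124	API125	API126	API127	API128	API129	API130	API131	API132	API133	API134	API135	API136	API137	API138	API139	API140	API141	API142	API143	API144	API145	API146	API147	API148	API149	API150	API151	API152	API153	API154	API155	API156	API157	API158	API159
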