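HSC_SIGNATURE_122_SYNTHETIC	synthetic stand-in: 122-gene HSC-specific signature (sizes and the single shared gene are real; other symbols are placeholders)	C1QTNF2	HSC001	HSC002	HSC003	HSC004	HSC005	HSC006	HSC007	HSC008	HSC009	HSC010	HSC011	HSC012	HSC013	HSC014	HSC015	HSC016	HSC017	HSC018	HSC019	HSC020	HSC021	HSC022	HSC023	HSC024	HSC025	HSC026	HSC027	HSC028	HSC029	HSC030	HSC031	HSC032	HSC033	HSC034	HSC035	HSC036	HSC037	HSC038	HSC039	HSC040	HSC041	HSC042	HSC043	HSC044	HSC045	HSC046	HSC047	HSC048	HSC049	HSC050	HSC051	HSC052	HSC053	HSC054	HSC055	HSC056	HSC057	HSC058	HSC059	HSC060	HSC061	HSC062	HSC063	HSC064	HSC065	HSC066	HSC067	HSC068	HSC069	HSC070	HSC071	HSC072	HSC073	HSC074	HSC075	HSC076	HSC077	HSC078	HSC079	HSC080	HSC081	HSC082	HSC083	HSC084	HSC085	HSC086	HSC087	HSC088	HSC089	HSC090	HSC091	HSC092	HSC093	HSC094	HSC095	HSC096	HSC097	HSC098	HSC099	HSC100	HSC101	HSC102	HSC103	HSC104	HSC105	HSC106	HSC107	HSC108	HSC109	HSC110	HSC111	HSC112	HSC113	HSC114	HSC115	HSC116	HSC117	HSC118	HSC119	HSC120	HSC121
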