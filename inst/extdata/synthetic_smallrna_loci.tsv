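group	locus_id	h3k27me3_target	detected_here
miRNA_single_locus	MIRS_001	1	1
miRNA_single_locus	MIRS_002	1	1
miRNA_single_locus	MIRS_003	1	1
miRNA_single_locus	MIRS_004	1	1
miRNA_single_locus	MIRS_005	1	1
miRNA_single_locus	MIRS_006	1	1
miRNA_single_locus	MIRS_007	1	1
miRNA_single_locus	MIRS_008	1	1
miRNA_single_locus	MIRS_009	1	1
miRNA_single_locus	MIRS_010	1	1
miRNA_single_locus	MIRS_011	1	1
miRNA_single_locus	MIRS_012	1	1
miRNA_single_locus	MIRS_013	1	1
miRNA_single_locus	MIRS_014	1	1
miRNA_single_locus	MIRS_015	1	1
miRNA_single_locus	MIRS_016	1	1
miRNA_single_locus	MIRS_017	1	1
miRNA_single_locus	MIRS_018	0	0
miRNA_single_locus	MIRS_019	0	0
miRNA_single_locus	MIRS_020	0	0
miRNA_single_locus	MIRS_021	0	0
miRNA_single_locus	MIRS_022	0	0
miRNA_single_locus	MIRS_023	0	0
miRNA_single_locus	MIRS_024	0	0
miRNA_single_locus	MIRS_025	0	0
miRNA_single_locus	MIRS_026	0	0
miRNA_single_locus	MIRS_027	0	0
miRNA_single_locus	MIRS_028	0	0
miRNA_single_locus	MIRS_029	0	0
miRNA_single_locus	MIRS_030	0	0
miRNA_single_locus	MIRS_031	0	0
miRNA_single_locus	MIRS_032	0	0
miRNA_single_locus	MIRS_033	0	0
miRNA_single_locus	MIRS_034	0	0
miRNA_single_locus	MIRS_035	0	0
miRNA_single_locus	MIRS_036	0	0
miRNA_single_locus	MIRS_037	0	0
miRNA_single_locus	MIRS_038	0	0
miRNA_single_locus	MIRS_039	0	0
miRNA_single_locus	MIRS_040	0	0
miRNA_single_locus	MIRS_041	0	0
miRNA_single_locus	MIRS_042	0	0
miRNA_single_locus	MIRS_043	0	0
miRNA_single_locus	MIRS_044	0	0
miRNA_single_locus	MIRS_045	0	0
miRNA_single_locus	MIRS_046	0	0
miRNA_single_locus	MIRS_047	0	0
miRNA_single_locus	MIRS_048	0	0
miRNA_single_locus	MIRS_049	0	0
miRNA_single_locus	MIRS_050	0	0
miRNA_single_locus	MIRS_051	0	0
miRNA_single_locus	MIRS_052	0	0
miRNA_single_locus	MIRS_053	0	0
miRNA_single_locus	MIRS_054	0	0
miRNA_single_locus	MIRS_055	0	0
miRNA_single_locus	MIRS_056	0	0
miRNA_single_locus	MIRS_057	0	0
miRNA_single_locus	MIRS_058	0	0
miRNA_single_locus	MIRS_059	0	0
miRNA_single_locus	MIRS_060	0	0
miRNA_single_locus	MIRS_061	0	0
miRNA_single_locus	MIRS_062	0	0
miRNA_single_locus	MIRS_063	0	0
miRNA_single_locus	MIRS_064	0	0
miRNA_single_locus	MIRS_065	0	0
miRNA_single_locus	MIRS_066	0	0
miRNA_single_locus	MIRS_067	0	0
miRNA_single_locus	MIRS_068	0	0
miRNA_single_locus	MIRS_069	0	0
miRNA_single_locus	MIRS_070	0	0
miRNA_single_locus	MIRS_071	0	0
miRNA_single_locus	MIRS_072	0	0
miRNA_single_locus	MIRS_073	0	0
miRNA_single_locus	MIRS_074	0	0
miRNA_single_locus	MIRS_075	0	0
miRNA_single_locus	MIRS_076	0	0
miRNA_single_locus	MIRS_077	0	0
miRNA_single_locus	MIRS_078	0	0
miRNA_multi_locus	MIRM_001	1	1
miRNA_multi_locus	MIRM_002	1	1
miRNA_multi_locus	MIRM_003	1	1
miRNA_multi_locus	MIRM_004	1	1
miRNA_multi_locus	MIRM_005	1	1
miRNA_multi_locus	MIRM_006	1	1
miRNA_multi_locus	MIRM_007	1	1
miRNA_multi_locus	MIRM_008	1	1
miRNA_multi_locus	MIRM_009	1	1
miRNA_multi_locus	MIRM_010	1	1
miRNA_multi_locus	MIRM_011	1	1
miRNA_multi_locus	MIRM_012	1	1
miRNA_multi_locus	MIRM_013	1	1
miRNA_multi_locus	MIRM_014	1	1
miRNA_multi_locus	MIRM_015	1	1
miRNA_multi_locus	MIRM_016	1	1
miRNA_multi_locus	MIRM_017	1	1
miRNA_multi_locus	MIRM_018	1	1
miRNA_multi_locus	MIRM_019	1	1
miRNA_multi_locus	MIRM_020	1	1
miRNA_multi_locus	MIRM_021	1	1
miRNA_multi_locus	MIRM_022	1	1
miRNA_multi_locus	MIRM_023	1	1
miRNA_multi_locus	MIRM_024	1	1
miRNA_multi_locus	MIRM_025	1	1
miRNA_multi_locus	MIRM_026	1	1
miRNA_multi_locus	MIRM_027	1	1
miRNA_multi_locus	MIRM_028	1	1
miRNA_multi_locus	MIRM_029	1	1
miRNA_multi_locus	MIRM_030	1	1
miRNA_multi_locus	MIRM_031	1	1
miRNA_multi_locus	MIRM_032	1	1
miRNA_multi_locus	MIRM_033	1	1
miRNA_multi_locus	MIRM_034	1	1
miRNA_multi_locus	MIRM_035	1	1
miRNA_multi_locus	MIRM_036	1	1
miRNA_multi_locus	MIRM_037	1	1
miRNA_multi_locus	MIRM_038	1	1
miRNA_multi_locus	MIRM_039	1	1
miRNA_multi_locus	MIRM_040	1	1
miRNA_multi_locus	MIRM_041	1	1
miRNA_multi_locus	MIRM_042	1	1
miRNA_multi_locus	MIRM_043	1	1
miRNA_multi_locus	MIRM_044	1	1
miRNA_multi_locus	MIRM_045	1	1
miRNA_multi_locus	MIRM_046	1	1
miRNA_multi_locus	MIRM_047	1	1
miRNA_multi_locus	MIRM_048	1	1
miRNA_multi_locus	MIRM_049	1	1
miRNA_multi_locus	MIRM_050	1	1
miRNA_multi_locus	MIRM_051	1	1
miRNA_multi_locus	MIRM_052	1	1
miRNA_multi_locus	MIRM_053	1	1
miRNA_multi_locus	MIRM_054	1	1
miRNA_multi_locus	MIRM_055	1	1
miRNA_multi_locus	MIRM_056	1	1
miRNA_multi_locus	MIRM_057	1	1
miRNA_multi_locus	MIRM_058	1	0
miRNA_multi_locus	MIRM_059	1	0
miRNA_multi_locus	MIRM_060	1	0
miRNA_multi_locus	MIRM_061	1	0
miRNA_multi_locus	MIRM_062	1	0
miRNA_multi_locus	MIRM_063	1	0
miRNA_multi_locus	MIRM_064	1	0
miRNA_multi_locus	MIRM_065	1	0
miRNA_multi_locus	MIRM_066	1	0
miRNA_multi_locus	MIRM_067	1	0
miRNA_multi_locus	MIRM_068	1	0
miRNA_multi_locus	MIRM_069	1	0
miRNA_multi_locus	MIRM_070	0	0
miRNA_multi_locus	MIRM_071	0	0
miRNA_multi_locus	MIRM_072	0	0
miRNA_multi_locus	MIRM_073	0	0
miRNA_multi_locus	MIRM_074	0	0
miRNA_multi_locus	MIRM_075	0	0
miRNA_multi_locus	MIRM_076	0	0
miRNA_multi_locus	MIRM_077	0	0
miRNA_multi_locus	MIRM_078	0	0
miRNA_multi_locus	MIRM_079	0	0
miRNA_multi_locus	MIRM_080	0	0
miRNA_multi_locus	MIRM_081	0	0
miRNA_multi_locus	MIRM_082	0	0
miRNA_multi_locus	MIRM_083	0	0
miRNA_multi_locus	MIRM_084	0	0
miRNA_multi_locus	MIRM_085	0	0
miRNA_multi_locus	MIRM_086	0	0
miRNA_multi_locus	MIRM_087	0	0
miRNA_multi_locus	MIRM_088	0	0
miRNA_multi_locus	MIRM_089	0	0
miRNA_multi_locus	MIRM_090	0	0
miRNA_multi_locus	MIRM_091	0	0
miRNA_multi_locus	MIRM_092	0	0
miRNA_multi_locus	MIRM_093	0	0
miRNA_multi_locus	MIRM_094	0	0
miRNA_multi_locus	MIRM_095	0	0
miRNA_multi_locus	MIRM_096	0	0
tasiRNA	TAS_001	1	0
tasiRNA	TAS_002	1	0
tasiRNA	TAS_003	0	0
tasiRNA	TAS_004	0	0
tasiRNA	TAS_005	0	0
tasiRNA	TAS_006	0	0
tasiRNA	TAS_007	0	0
tasiRNA	TAS_008	0	0
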