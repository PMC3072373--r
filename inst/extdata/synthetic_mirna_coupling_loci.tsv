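family	locus_id	h3k27me3_target
miR394	LmiR394_001	1
miR394	LmiR394_002	1
miR845	LmiR845_001	1
miR845	LmiR845_002	1
miR164	LmiR164_001	1
miR164	LmiR164_002	1
miR164	LmiR164_003	1
miR158	LmiR158_001	1
miR158	LmiR158_002	1
miR166/165	LmiR166_165_001	1
miR166/165	LmiR166_165_002	1
miR166/165	LmiR166_165_003	1
miR166/165	LmiR166_165_004	1
miR166/165	LmiR166_165_005	1
miR166/165	LmiR166_165_006	1
miR166/165	LmiR166_165_007	1
miR166/165	LmiR166_165_008	1
miR166/165	LmiR166_165_009	0
miR169	LmiR169_001	1
miR169	LmiR169_002	1
miR169	LmiR169_003	1
miR169	LmiR169_004	1
miR169	LmiR169_005	1
miR169	LmiR169_006	1
miR169	LmiR169_007	1
miR169	LmiR169_008	1
miR169	LmiR169_009	1
miR169	LmiR169_010	1
miR169	LmiR169_011	1
miR169	LmiR169_012	1
miR169	LmiR169_013	0
miR169	LmiR169_014	0
miR395	LmiR395_001	1
miR395	LmiR395_002	1
miR395	LmiR395_003	1
miR395	LmiR395_004	1
miR395	LmiR395_005	1
miR395	LmiR395_006	0
miR399	LmiR399_001	1
miR399	LmiR399_002	1
miR399	LmiR399_003	1
miR399	LmiR399_004	1
miR399	LmiR399_005	1
miR399	LmiR399_006	0
miR156/157	LmiR156_157_001	1
miR156/157	LmiR156_157_002	1
miR156/157	LmiR156_157_003	1
miR156/157	LmiR156_157_004	1
miR156/157	LmiR156_157_005	1
miR156/157	LmiR156_157_006	1
miR156/157	LmiR156_157_007	1
miR156/157	LmiR156_157_008	1
miR156/157	LmiR156_157_009	1
miR156/157	LmiR156_157_010	1
miR156/157	LmiR156_157_011	0
miR156/157	LmiR156_157_012	0
miR172	LmiR172_001	1
miR172	LmiR172_002	1
miR172	LmiR172_003	1
miR172	LmiR172_004	1
miR172	LmiR172_005	0
miR160/167	LmiR160_167_001	1
miR160/167	LmiR160_167_002	1
miR160/167	LmiR160_167_003	1
miR160/167	LmiR160_167_004	1
miR160/167	LmiR160_167_005	1
miR160/167	LmiR160_167_006	0
miR160/167	LmiR160_167_007	0
miR159/319	LmiR159_319_001	1
miR159/319	LmiR159_319_002	1
miR159/319	LmiR159_319_003	1
miR159/319	LmiR159_319_004	1
miR159/319	LmiR159_319_005	0
miR159/319	LmiR159_319_006	0
miR171	LmiR171_001	1
miR171	LmiR171_002	1
miR171	LmiR171_003	0
miR393	LmiR393_001	1
miR393	LmiR393_002	0
miR168	LmiR168_001	1
miR168	LmiR168_002	0
miR397	LmiR397_001	1
miR397	LmiR397_002	0
miR390	LmiR390_001	1
miR390	LmiR390_002	0
miR447	LmiR447_001	1
miR447	LmiR447_002	0
miR447	LmiR447_003	0
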