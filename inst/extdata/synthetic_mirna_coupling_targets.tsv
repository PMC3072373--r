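family	target_id	h3k27me3_target
miR394	TmiR394_001	0
miR164	TmiR164_001	1
miR164	TmiR164_002	1
miR164	TmiR164_003	0
miR164	TmiR164_004	0
miR164	TmiR164_005	0
miR164	TmiR164_006	0
miR164	TmiR164_007	0
miR158	TmiR158_001	1
miR158	TmiR158_002	1
miR158	TmiR158_003	1
miR158	TmiR158_004	0
miR158	TmiR158_005	0
miR158	TmiR158_006	0
miR158	TmiR158_007	0
miR158	TmiR158_008	0
miR158	TmiR158_009	0
miR158	TmiR158_010	0
miR158	TmiR158_011	0
miR158	TmiR158_012	0
miR158	TmiR158_013	0
miR158	TmiR158_014	0
miR158	TmiR158_015	0
miR158	TmiR158_016	0
miR158	TmiR158_017	0
miR158	TmiR158_018	0
miR158	TmiR158_019	0
miR158	TmiR158_020	0
miR158	TmiR158_021	0
miR158	TmiR158_022	0
miR166/165	TmiR166_165_001	1
miR166/165	TmiR166_165_002	1
miR166/165	TmiR166_165_003	0
miR166/165	TmiR166_165_004	0
miR166/165	TmiR166_165_005	0
miR169	TmiR169_001	0
miR169	TmiR169_002	0
miR169	TmiR169_003	0
miR169	TmiR169_004	0
miR169	TmiR169_005	0
miR169	TmiR169_006	0
miR169	TmiR169_007	0
miR395	TmiR395_001	1
miR395	TmiR395_002	0
miR395	TmiR395_003	0
miR395	TmiR395_004	0
miR399	TmiR399_001	0
miR156/157	TmiR156_157_001	1
miR156/157	TmiR156_157_002	0
miR156/157	TmiR156_157_003	0
miR156/157	TmiR156_157_004	0
miR156/157	TmiR156_157_005	0
miR156/157	TmiR156_157_006	0
miR156/157	TmiR156_157_007	0
miR156/157	TmiR156_157_008	0
miR156/157	TmiR156_157_009	0
miR156/157	TmiR156_157_010	0
miR156/157	TmiR156_157_011	0
miR172	TmiR172_001	1
miR172	TmiR172_002	1
miR172	TmiR172_003	0
miR172	TmiR172_004	0
miR172	TmiR172_005	0
miR172	TmiR172_006	0
miR160/167	TmiR160_167_001	0
miR160/167	TmiR160_167_002	0
miR160/167	TmiR160_167_003	0
miR160/167	TmiR160_167_004	0
miR160/167	TmiR160_167_005	0
miR159/319	TmiR159_319_001	1
miR159/319	TmiR159_319_002	1
miR159/319	TmiR159_319_003	1
miR159/319	TmiR159_319_004	1
miR159/319	TmiR159_319_005	1
miR159/319	TmiR159_319_006	0
miR159/319	TmiR159_319_007	0
miR159/319	TmiR159_319_008	0
miR159/319	TmiR159_319_009	0
miR159/319	TmiR159_319_010	0
miR159/319	TmiR159_319_011	0
miR159/319	TmiR159_319_012	0
miR171	TmiR171_001	1
miR171	TmiR171_002	0
miR171	TmiR171_003	0
miR393	TmiR393_001	0
miR393	TmiR393_002	0
miR393	TmiR393_003	0
miR393	TmiR393_004	0
miR393	TmiR393_005	0
miR168	TmiR168_001	0
miR397	TmiR397_001	1
miR397	TmiR397_002	1
miR397	TmiR397_003	0
miR390	TmiR390_001	1
miR390	TmiR390_002	1
miR390	TmiR390_003	0
miR447	TmiR447_001	1
miR447	TmiR447_002	0
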