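rule_id	side	tier	pvs_min	ps_min	pm_min	pp_min	ba_min	bs_min	bp_min
P-1	pathogenic	Pathogenic	1	1	0	0	0	0	0
P-2	pathogenic	Pathogenic	1	0	2	0	0	0	0
P-3	pathogenic	Pathogenic	1	0	1	1	0	0	0
P-4	pathogenic	Pathogenic	1	0	0	2	0	0	0
P-5	pathogenic	Pathogenic	0	2	0	0	0	0	0
P-6	pathogenic	Pathogenic	0	1	3	0	0	0	0
P-7	pathogenic	Pathogenic	0	1	2	2	0	0	0
P-8	pathogenic	Pathogenic	0	1	1	4	0	0	0
LP-1	pathogenic	LikelyPathogenic	1	0	1	0	0	0	0
LP-2	pathogenic	LikelyPathogenic	0	1	1	0	0	0	0
LP-3	pathogenic	LikelyPathogenic	0	1	0	2	0	0	0
LP-4	pathogenic	LikelyPathogenic	0	0	3	0	0	0	0
LP-5	pathogenic	LikelyPathogenic	0	0	2	2	0	0	0
LP-6	pathogenic	LikelyPathogenic	0	0	1	4	0	0	0
B-1	benign	Benign	0	0	0	0	1	0	0
B-2	benign	Benign	0	0	0	0	0	2	0
LB-1	benign	LikelyBenign	0	0	0	0	0	1	1
LB-2	benign	LikelyBenign	0	0	0	0	0	0	2
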