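id	chrom	pos	ref	alt	gene	consequence	freq_1000g	freq_evs	freq_exac	freq_inhouse	pred_polyphen	pred_sift	pred_cadd	gt_FA	gt_MO	gt_P1	gt_S1	note
common_01	chr21	43810000	C	T	GENE001	missense	NA	0.05	NA	NA	damaging	damaging	damaging	1	1	2	0	common
common_02	chr21	43820000	G	A	GENE002	missense	NA	NA	0.002	NA	damaging	damaging	damaging	1	1	2	0	common
common_03	chr21	43830000	T	C	GENE003	missense	NA	NA	NA	0.001	damaging	damaging	damaging	1	1	2	0	common
common_04	chr21	43840000	A	G	GENE004	missense	0.31	NA	NA	NA	damaging	damaging	damaging	1	1	2	0	common
common_05	chr21	43850000	C	T	GENE005	missense	NA	0.05	NA	NA	damaging	damaging	damaging	1	1	2	0	common
common_06	chr21	43860000	G	A	GENE006	missense	NA	NA	0.002	NA	damaging	damaging	damaging	1	1	2	0	common
common_07	chr21	43870000	T	C	GENE007	missense	NA	NA	NA	0.001	damaging	damaging	damaging	1	1	2	0	common
common_08	chr21	43880000	A	G	GENE008	missense	0.31	NA	NA	NA	damaging	damaging	damaging	1	1	2	0	common
common_09	chr21	43890000	C	T	GENE009	missense	NA	0.05	NA	NA	damaging	damaging	damaging	1	1	2	0	common
common_10	chr21	43900000	G	A	GENE010	missense	NA	NA	0.002	NA	damaging	damaging	damaging	1	1	2	0	common
common_11	chr21	43910000	T	C	GENE011	missense	NA	NA	NA	0.001	damaging	damaging	damaging	1	1	2	0	common
common_12	chr21	43920000	A	G	GENE012	missense	0.31	NA	NA	NA	damaging	damaging	damaging	1	1	2	0	common
common_13	chr21	43930000	C	T	GENE013	missense	NA	0.05	NA	NA	damaging	damaging	damaging	1	1	2	0	common
common_14	chr21	43940000	G	A	GENE014	missense	NA	NA	0.002	NA	damaging	damaging	damaging	1	1	2	0	common
common_15	chr21	43950000	T	C	GENE015	missense	NA	NA	NA	0.001	damaging	damaging	damaging	1	1	2	0	common
het_01	chr21	43960000	A	G	GENE016	missense	5e-05	NA	NA	NA	damaging	damaging	damaging	1	0	1	0	het
het_02	chr21	43970000	C	T	GENE017	missense	NA	NA	NA	NA	damaging	damaging	damaging	1	0	1	0	het
het_03	chr21	43980000	G	A	GENE018	missense	NA	NA	NA	NA	damaging	damaging	damaging	1	0	1	0	het
het_04	chr21	43990000	T	C	GENE019	missense	NA	NA	NA	NA	damaging	damaging	damaging	1	0	1	0	het
het_05	chr21	4.4e+07	A	G	GENE020	missense	NA	NA	NA	NA	damaging	damaging	damaging	1	0	1	0	het
het_06	chr21	44010000	C	T	GENE021	missense	NA	NA	NA	NA	damaging	damaging	damaging	1	0	1	0	het
het_07	chr21	44020000	G	A	GENE022	missense	NA	NA	NA	NA	damaging	damaging	damaging	1	0	1	0	het
missing_01	chr21	44030000	T	C	GENE023	missense	NA	NA	NA	NA	damaging	damaging	damaging	1	1	NA	0	missing_gt
outside_01	chr20	1050000	A	G	GENE024	missense	NA	NA	NA	NA	damaging	damaging	damaging	1	1	2	0	outside
outside_02	chr20	1100000	C	T	GENE025	missense	NA	NA	NA	NA	damaging	damaging	damaging	1	1	2	0	outside
outside_03	chr21	43809417	G	A	GENE026	missense	NA	NA	NA	NA	damaging	damaging	damaging	1	1	2	0	outside
outside_04	chr21	44828032	T	C	GENE027	missense	NA	NA	NA	NA	damaging	damaging	damaging	1	1	2	0	outside
outside_05	chr21	42500000	A	G	GENE028	missense	NA	NA	NA	NA	damaging	damaging	damaging	1	1	2	0	outside
outside_06	chr21	42600000	C	T	GENE029	missense	NA	NA	NA	NA	damaging	damaging	damaging	1	1	2	0	outside
outside_07	chr21	42700000	G	A	GENE030	missense	NA	NA	NA	NA	damaging	damaging	damaging	1	1	2	0	outside
syn_01	chr21	44040000	T	C	GENE031	synonymous	NA	NA	NA	NA	NA	NA	NA	1	1	2	0	synonymous
syn_02	chr21	44050000	A	G	GENE032	synonymous	NA	NA	NA	NA	NA	NA	NA	1	1	2	0	synonymous
syn_03	chr21	44060000	C	T	GENE033	synonymous	NA	NA	NA	NA	NA	NA	NA	1	1	2	0	synonymous
syn_04	chr21	44070000	G	A	GENE034	synonymous	NA	NA	NA	NA	NA	NA	NA	1	1	2	0	synonymous
nc_01	chr21	44080000	T	C	GENE035	noncoding	NA	NA	NA	NA	NA	NA	NA	1	1	2	0	noncoding
nc_02	chr21	44090000	A	G	GENE036	noncoding	NA	NA	NA	NA	NA	NA	NA	1	1	2	0	noncoding
benign_01	chr21	44100000	C	T	GENE037	missense	NA	NA	NA	NA	benign	benign	damaging	1	1	2	0	benign
benign_02	chr21	44110000	G	A	GENE038	missense	NA	NA	NA	NA	benign	benign	benign	1	1	2	0	benign
benign_03	chr21	44120000	T	C	GENE039	missense	NA	NA	NA	NA	benign	NA	NA	1	1	2	0	benign
benign_04	chr21	44130000	A	G	GENE040	missense	NA	NA	NA	NA	damaging	NA	NA	1	1	2	0	benign
benign_05	chr21	44140000	C	T	GENE041	missense	NA	NA	NA	NA	NA	benign	benign	1	1	2	0	benign
benign_06	chr21	44150000	G	A	GENE042	missense	NA	NA	NA	NA	NA	NA	NA	1	1	2	0	benign
surv_missense_01	chr21	43809418	T	C	GENE043	missense	NA	NA	NA	NA	damaging	damaging	damaging	1	1	2	1	survivor
surv_missense_02	chr21	44828031	A	G	GENE044	missense	NA	NA	NA	NA	damaging	damaging	benign	1	1	2	0	survivor
surv_missense_03	chr21	44160000	C	T	GENE045	missense	5e-05	NA	NA	NA	damaging	damaging	NA	1	1	2	1	survivor
surv_inframe_01	chr21	44170000	G	A	GENE046	inframe_indel	NA	NA	NA	NA	damaging	damaging	damaging	1	1	2	0	survivor
surv_frameshift_01	chr21	44180000	T	C	GENE047	frameshift	NA	NA	NA	NA	NA	NA	NA	1	1	2	1	survivor_lof_bypass
surv_nonsense_01	chr21	44190000	A	G	GENE048	nonsense	NA	NA	NA	NA	benign	benign	benign	1	1	2	0	survivor_lof_bypass
surv_nonseg_01	chr21	44200000	C	T	GENE049	missense	NA	NA	NA	NA	damaging	damaging	damaging	1	1	2	2	survivor_nonsegregating
surv_uninf_01	chr21	44210000	G	A	GENE050	splicing	NA	NA	NA	NA	damaging	damaging	damaging	NA	NA	2	NA	survivor_uninformative
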