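ProteinName	FullPeptideName	Charge	filename	RT	Intensity	m_score	decoy	aggr_Fragment_Annotation	aggr_Peak_Area
1/spA	AGLNDTWVK	2	demo_plasma0_rep1_001.mzML	2575.9	17639.99	0.00024943	0	p2_y4_1;p2_y6_1;p2_y7_1	4180.94;5126.0;8333.05
1/spA	AGLNDTWVK	2	demo_plasma0_rep2_002.mzML	3516.8	11898.8	0.00077562	0	p2_y4_1;p2_y6_1;p2_y7_1	5368.99;1825.01;4704.8
1/spA	AGLNDTWVK	2	demo_plasma10_rep1_003.mzML	3188.3	4896.12	0.00268493	0	p2_y4_1;p2_y6_1;p2_y7_1	1028.29;2869.93;997.9
1/spA	AGLNDTWVK	2	demo_plasma10_rep2_004.mzML	2931.4	18101.72	0.00091573	0	p2_y4_1;p2_y6_1;p2_y7_1	568.55;8843.3;8689.87
1/spA	ELFTTPGSR	2	demo_plasma0_rep1_001.mzML	1527.7	6767.72	1.509e-05	0	p2_y4_1;p2_y6_1;p2_y7_1	1585.95;332.01;4849.76
1/spA	ELFTTPGSR	2	demo_plasma0_rep2_002.mzML	3680.0	7076.45	0.0002097	0	p2_y4_1;p2_y6_1;p2_y7_1	2329.1;464.73;4282.62
1/spA	ELFTTPGSR	2	demo_plasma10_rep1_003.mzML	2409.2	15200.86	0.00097129	0	p2_y4_1;p2_y6_1;p2_y7_1	4768.29;5834.57;4598.0
1/spA	ELFTTPGSR	2	demo_plasma10_rep2_004.mzML	3235.8	20589.29	0.00331625	0	p2_y4_1;p2_y6_1;p2_y7_1	2647.83;8979.37;8962.09
2/spA/spB	VLDPTHFMK	2	demo_plasma0_rep1_001.mzML	3428.8	7939.05	1.624e-05	0	p2_y4_1;p2_y6_1;p2_y7_1	2974.44;2221.06;2743.55
2/spA/spB	VLDPTHFMK	2	demo_plasma0_rep2_002.mzML	3696.1	14974.78	0.00748389	0	p2_y4_1;p2_y6_1;p2_y7_1	3723.52;7649.94;3601.32
2/spA/spB	VLDPTHFMK	2	demo_plasma10_rep1_003.mzML	4135.2	10460.7	0.00025702	0	p2_y4_1;p2_y6_1;p2_y7_1	204.8;2045.51;8210.39
2/spA/spB	VLDPTHFMK	2	demo_plasma10_rep2_004.mzML	1790.3	10279.27	0.00216537	0	p2_y4_1;p2_y6_1;p2_y7_1	3697.33;842.74;5739.2
1/spB	TSEYGIFNR	3	demo_plasma0_rep1_001.mzML	1289.4	12777.49	0.00187984	0	p3_y4_1;p3_y6_1;p3_y7_1	966.87;3126.75;8683.87
1/spB	TSEYGIFNR	3	demo_plasma0_rep2_002.mzML	1486.3	4184.48	0.00246073	0	p3_y4_1;p3_y6_1;p3_y7_1	2368.21;1089.21;727.06
1/spB	TSEYGIFNR	3	demo_plasma10_rep1_003.mzML	1332.2	11137.16	0.00156922	0	p3_y4_1;p3_y6_1;p3_y7_1	5121.8;4137.34;1878.02
1/spB	TSEYGIFNR	3	demo_plasma10_rep2_004.mzML	1790.3	10992.61	4.351e-05	0	p3_y4_1;p3_y6_1;p3_y7_1	5864.69;1225.27;3902.65
DECOY_1/spA	KVWTDNLGA	2	demo_plasma0_rep1_001.mzML	1595.3	18890.68	0.8021	1	p2_y4_1;p2_y6_1;p2_y7_1	8744.18;7270.02;2876.48
DECOY_1/spA	KVWTDNLGA	2	demo_plasma0_rep2_002.mzML	4164.7	17236.29	0.1353	1	p2_y4_1;p2_y6_1;p2_y7_1	3669.62;7718.52;5848.15
DECOY_1/spA	KVWTDNLGA	2	demo_plasma10_rep1_003.mzML	1877.9	11549.05	0.3296	1	p2_y4_1;p2_y6_1;p2_y7_1	2076.54;2472.84;6999.67
DECOY_1/spA	KVWTDNLGA	2	demo_plasma10_rep2_004.mzML	2884.2	7167.01	0.2566	1	p2_y4_1;p2_y6_1;p2_y7_1	845.91;993.03;5328.07
DECOY_1/spB	RNFIGYEST	3	demo_plasma0_rep1_001.mzML	2796.1	16299.62	0.4612	1	p3_y4_1;p3_y6_1;p3_y7_1	3471.0;4188.23;8640.39
DECOY_1/spB	RNFIGYEST	3	demo_plasma0_rep2_002.mzML	3598.7	11190.7	0.8222	1	p3_y4_1;p3_y6_1;p3_y7_1	7825.43;1808.88;1556.39
DECOY_1/spB	RNFIGYEST	3	demo_plasma10_rep1_003.mzML	1548.7	10972.77	0.8493	1	p3_y4_1;p3_y6_1;p3_y7_1	2395.59;1870.25;6706.93
DECOY_1/spB	RNFIGYEST	3	demo_plasma10_rep2_004.mzML	1242.7	22035.57	0.4082	1	p3_y4_1;p3_y6_1;p3_y7_1	8561.2;7963.27;5511.1
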