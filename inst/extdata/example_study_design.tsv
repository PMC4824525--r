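Filename	Condition	BioReplicate	Run
demo_plasma0_rep1_001.mzML	plasma0	1	demo_plasma0_rep1_001.mzML
demo_plasma0_rep2_002.mzML	plasma0	2	demo_plasma0_rep2_002.mzML
demo_plasma10_rep1_003.mzML	plasma10	1	demo_plasma10_rep1_003.mzML
demo_plasma10_rep2_004.mzML	plasma10	2	demo_plasma10_rep2_004.mzML
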