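read_id	transcript_id	condition	replicate	polya_length	qc_tag
txA_r1_001_PASS	txA	wt	1	46.85	PASS
txA_r1_002_PASS	txA	wt	1	37.18	PASS
txA_r1_003_PASS	txA	wt	1	41.82	PASS
txA_r1_004_PASS	txA	wt	1	43.16	PASS
txA_r1_005_PASS	txA	wt	1	42.02	PASS
txA_r1_006_PASS	txA	wt	1	39.47	PASS
txA_r1_007_PASS	txA	wt	1	47.56	PASS
txA_r1_008_PASS	txA	wt	1	39.53	PASS
txA_r1_009_PASS	txA	wt	1	50.09	PASS
txA_r1_010_PASS	txA	wt	1	39.69	PASS
txA_r1_011_PASS	txA	wt	1	46.52	PASS
txA_r1_012_PASS	txA	wt	1	51.43	PASS
txA_r1_013_PASS	txA	wt	1	33.06	PASS
txA_r1_014_PASS	txA	wt	1	38.61	PASS
txA_r1_015_PASS	txA	wt	1	39.33	PASS
txA_r1_016_PASS	txA	wt	1	43.18	PASS
txA_r1_017_PASS	txA	wt	1	38.58	PASS
txA_r1_018_PASS	txA	wt	1	26.72	PASS
txA_r1_019_PASS	txA	wt	1	27.8	PASS
txA_r1_020_PASS	txA	wt	1	46.6	PASS
txA_r2_001_PASS	txA	wt	2	38.47	PASS
txA_r2_002_PASS	txA	wt	2	31.09	PASS
txA_r2_003_PASS	txA	wt	2	39.14	PASS
txA_r2_004_PASS	txA	wt	2	46.07	PASS
txA_r2_005_PASS	txA	wt	2	49.48	PASS
txA_r2_006_PASS	txA	wt	2	37.85	PASS
txA_r2_007_PASS	txA	wt	2	38.71	PASS
txA_r2_008_PASS	txA	wt	2	31.18	PASS
txA_r2_009_PASS	txA	wt	2	42.3	PASS
txA_r2_010_PASS	txA	wt	2	36.8	PASS
txA_r2_011_PASS	txA	wt	2	42.28	PASS
txA_r2_012_PASS	txA	wt	2	43.52	PASS
txA_r2_013_PASS	txA	wt	2	45.18	PASS
txA_r2_014_PASS	txA	wt	2	36.96	PASS
txA_r2_015_PASS	txA	wt	2	42.52	PASS
txA_r2_016_PASS	txA	wt	2	31.41	PASS
txA_r2_017_PASS	txA	wt	2	36.08	PASS
txA_r2_018_PASS	txA	wt	2	35.75	PASS
txA_r2_019_PASS	txA	wt	2	27.93	PASS
txB_r1_001_PASS	txB	wt	1	60.18	PASS
txB_r1_002_PASS	txB	wt	1	61.03	PASS
txB_r1_003_PASS	txB	wt	1	58.19	PASS
txB_r1_004_PASS	txB	wt	1	63.79	PASS
txB_r1_005_PASS	txB	wt	1	56.37	PASS
txB_r1_006_PASS	txB	wt	1	53.16	PASS
txB_r1_007_PASS	txB	wt	1	62.16	PASS
txB_r1_008_PASS	txB	wt	1	55.94	PASS
txB_r1_009_PASS	txB	wt	1	67.22	PASS
txB_r1_010_PASS	txB	wt	1	57.84	PASS
txB_r1_011_PASS	txB	wt	1	63.28	PASS
txB_r1_012_PASS	txB	wt	1	61.61	PASS
txB_r1_013_PASS	txB	wt	1	56.08	PASS
txB_r1_014_PASS	txB	wt	1	67.88	PASS
txB_r1_015_PASS	txB	wt	1	63.21	PASS
txB_r1_016_PASS	txB	wt	1	60.45	PASS
txB_r1_017_PASS	txB	wt	1	61.38	PASS
txB_r1_018_PASS	txB	wt	1	63.4	PASS
txB_r1_019_PASS	txB	wt	1	60.45	PASS
txB_r1_020_PASS	txB	wt	1	45.03	PASS
txB_r1_021_PASS	txB	wt	1	61.42	PASS
txB_r2_001_PASS	txB	wt	2	58.16	PASS
txB_r2_002_PASS	txB	wt	2	60.93	PASS
txB_r2_003_PASS	txB	wt	2	62.91	PASS
txB_r2_004_PASS	txB	wt	2	67	PASS
txB_r2_005_PASS	txB	wt	2	56.36	PASS
txB_r2_006_PASS	txB	wt	2	66.51	PASS
txB_r2_007_PASS	txB	wt	2	61.68	PASS
txB_r2_008_PASS	txB	wt	2	65.19	PASS
txB_r2_009_PASS	txB	wt	2	64.6	PASS
txB_r2_010_PASS	txB	wt	2	63.6	PASS
txB_r2_011_PASS	txB	wt	2	54.78	PASS
txB_r2_012_PASS	txB	wt	2	59.55	PASS
txB_r2_013_PASS	txB	wt	2	63.12	PASS
txB_r2_014_PASS	txB	wt	2	55.23	PASS
txB_r2_015_PASS	txB	wt	2	57.29	PASS
txB_r2_016_PASS	txB	wt	2	62.9	PASS
txB_r2_017_PASS	txB	wt	2	63.84	PASS
txB_r2_018_PASS	txB	wt	2	62.32	PASS
txB_r2_019_PASS	txB	wt	2	55.57	PASS
txB_r2_020_PASS	txB	wt	2	54.5	PASS
txA_r1_001_SUFFCLIP	txA	wt	1	47.56	SUFFCLIP
txA_r1_002_SUFFCLIP	txA	wt	1	41.29	SUFFCLIP
txA_r1_003_SUFFCLIP	txA	wt	1	40.44	SUFFCLIP
txA_r1_004_SUFFCLIP	txA	wt	1	39.4	SUFFCLIP
txA_r1_005_SUFFCLIP	txA	wt	1	34.03	SUFFCLIP
txA_r1_006_SUFFCLIP	txA	wt	1	43.06	SUFFCLIP
txA_r2_001_SUFFCLIP	txA	wt	2	38.91	SUFFCLIP
txA_r2_002_SUFFCLIP	txA	wt	2	39.09	SUFFCLIP
txA_r2_003_SUFFCLIP	txA	wt	2	44.67	SUFFCLIP
txA_r2_004_SUFFCLIP	txA	wt	2	44.11	SUFFCLIP
txA_r2_005_SUFFCLIP	txA	wt	2	46.96	SUFFCLIP
txB_r1_001_SUFFCLIP	txB	wt	1	57.62	SUFFCLIP
txB_r1_002_SUFFCLIP	txB	wt	1	63.25	SUFFCLIP
txB_r1_003_SUFFCLIP	txB	wt	1	66.96	SUFFCLIP
txB_r1_004_SUFFCLIP	txB	wt	1	54.45	SUFFCLIP
txB_r1_005_SUFFCLIP	txB	wt	1	55.7	SUFFCLIP
txB_r2_001_SUFFCLIP	txB	wt	2	54.34	SUFFCLIP
txB_r2_002_SUFFCLIP	txB	wt	2	52.7	SUFFCLIP
txB_r2_003_SUFFCLIP	txB	wt	2	60.4	SUFFCLIP
txB_r2_004_SUFFCLIP	txB	wt	2	63.27	SUFFCLIP
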