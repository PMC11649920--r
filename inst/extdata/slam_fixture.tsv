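transcript_id	condition	replicate	time_min	read_count	conversion_rate
tx1	ctrl	1	0	100	0.05
tx1	ctrl	1	5	19	0.04
tx1	ctrl	1	10	100	0.03
tx1	ctrl	1	15	100	0.02
tx1	ctrl	1	20	100	5e-05
tx2	ctrl	1	0	100	0.06
tx2	ctrl	1	5	100	0.05
tx2	ctrl	1	10	19	0.04
tx2	ctrl	1	15	19	0.03
tx2	ctrl	1	20	100	0.02
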