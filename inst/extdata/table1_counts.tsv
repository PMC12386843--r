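region_id	sample	context	n_sites	n_unmethylated	printed_percent	conversion_rate_percent
Sdh3-1	day 1	CG	7	4	42.9	87.8
Sdh3-1	day 1	CNG	6	1	83.3	87.8
Sdh3-1	day 1	CNN	36	6	83.3	87.8
Sdh3-1	day 4	CG	7	4	42.9	84.1
Sdh3-1	day 4	CNG	6	2	66.7	84.1
Sdh3-1	day 4	CNN	36	8	77.7	84.1
Sdh3-1	day 8	CG	7	6	14.3	85.4
Sdh3-1	day 8	CNG	6	1	83.3	85.4
Sdh3-1	day 8	CNN	36	10	75.6	85.4
Sdh3-2	day 1	CG	20	2	90.0	81.1
Sdh3-2	day 1	CNG	12	3	75.5	81.1
Sdh3-2	day 1	CNN	48	26	45.8	81.1
Sdh3-2	day 4	CG	20	5	75.0	87.7
Sdh3-2	day 4	CNG	12	2	83.3	87.7
Sdh3-2	day 4	CNN	48	28	41.7	87.7
Sdh3-2	day 8	CG	20	11	45.0	84.5
Sdh3-2	day 8	CNG	12	8	33.3	84.5
Sdh3-2	day 8	CNN	48	21	56.3	84.5
Sdh4	day 1	CG	7	2	71.4	78.3
Sdh4	day 1	CNG	12	5	58.3	78.3
Sdh4	day 1	CNN	43	16	62.8	78.3
Sdh4	day 4	CG	7	2	71.4	80.7
Sdh4	day 4	CNG	12	5	58.3	80.7
Sdh4	day 4	CNN	43	15	65.1	80.7
Sdh4	day 8	CG	7	4	42.9	81.0
Sdh4	day 8	CNG	12	5	58.3	81.0
Sdh4	day 8	CNN	43	15	65.1	81.0
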