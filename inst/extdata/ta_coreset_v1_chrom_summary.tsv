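chrom	n_markers	max_interval_mb	mean_interval_mb	start_mb	end_mb	cover_size_mb	refseq_mb	coverage_pct
1A	47	65.9	12.8	3.4	591.2	587.8	594.1	98.9
2A	51	109.8	15.5	2.5	778.4	775.9	780.8	99.4
3A	42	115.3	17.8	13.9	743.8	729.9	750.8	97.2
4A	46	257.8	16.4	2.9	742.4	739.5	744.6	99.3
5A	49	112.6	14.4	0.3	689.9	689.6	709.8	97.2
6A	39	206.1	16.2	0.6	615.5	614.9	618.1	99.5
7A	52	174.3	14.2	8.4	733.4	725.0	736.7	98.4
1B	43	82.1	16.3	4.3	687.7	683.4	689.9	99.1
2B	51	116.9	15.7	4.6	789.9	785.3	801.3	98.0
3B	51	56.3	16.4	0.2	822.2	822.0	830.8	98.9
4B	41	180.8	16.7	1.8	670.4	668.6	673.6	99.3
5B	47	105.6	15.3	7.7	712.7	705.0	713.1	98.9
6B	52	47.1	14.1	0.2	718.9	718.7	721.0	99.7
7B	44	105.9	16.9	2.9	730.2	727.3	750.6	96.9
1D	38	132.7	13.3	0.9	494.2	493.3	495.5	99.6
2D	49	87.6	13.5	0.4	648.5	648.1	651.9	99.4
3D	40	84.0	15.6	5.0	613.4	608.4	615.6	98.8
4D	38	98.1	13.6	1.3	506.1	504.8	509.9	99.0
5D	50	70.8	11.5	0.6	562.7	562.1	566.1	99.3
6D	43	124.1	11.3	0.8	473.4	472.6	473.6	99.8
7D	39	112.8	16.6	1.3	631.8	630.5	638.7	98.7
Un	8	NA	NA	NA	NA	NA	481.0	NA
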