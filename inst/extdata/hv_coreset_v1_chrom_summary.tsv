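chrom	n_markers	max_interval_mb	mean_interval_mb	start_mb	end_mb	cover_size_mb	refseq_mb	coverage_pct
1H	104	20.1	5.4	1.4	556.5	555.1	558.5	99.4
2H	109	28.0	7.1	2.3	766.3	764.0	768.1	99.5
3H	110	21.0	6.4	0.1	699.1	699.0	699.7	99.9
4H	109	29.5	6.0	0.1	646.0	645.9	647.1	99.8
5H	116	31.3	5.8	0.4	669.6	669.2	670.0	99.9
6H	115	30.2	5.1	0.3	582.4	582.1	583.4	99.8
7H	105	27.0	6.3	0.6	656.1	655.5	657.2	99.7
Un	0	NA	NA	NA	NA	NA	249.8	NA
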