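name	total_length	contig_count	contig_n50	gap_count	masked_pct
Chromosome_1	42132932	3	24807925	2	43.18
Chromosome_2	48726069	3	22686334	2	43.03
Chromosome_3	49814079	3	26462178	2	47.83
Chromosome_4	39642072	2	21223292	1	53.00
Chromosome_5	46382547	4	25487884	3	39.71
Chromosome_6	36113639	6	11701730	5	54.03
Chromosome_7	35147422	8	8095101	7	41.38
Chromosome_8	42437421	13	7531332	12	56.60
Chromosome_9	56635340	2	29513894	1	39.28
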