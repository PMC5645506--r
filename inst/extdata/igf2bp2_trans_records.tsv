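rsid	snp_chrom	snp_pos_approx	gene_name	gene_chrom	gene_tss	tissue	p_value	q_value	cell_line
rs13100823	3	185400000	RBM47	4	40425272	Whole_Blood	1.68e-05	0.049	HUVEC
rs11705729	3	185410000	KIAA1430	4	186080819	Hypothalamus	1.18e-05	0.036	NHEK
rs11927381	3	185420000	DIS3L2	2	232825955	Lung	1.08e-05	0.034	NHEK
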