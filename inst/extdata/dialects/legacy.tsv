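rsid	chrom	position	effect_allele	non_effect_allele	eaf	beta	stderr	pval
rs501	5	51200	A	T	0.28	0.006	0.002	0.0027
rs502	8	80455	C	G	0.51	-0.001	0.0021	0.63
rs503	12	121077	T	A	0.09	0.014	0.0035	6.4e-5
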