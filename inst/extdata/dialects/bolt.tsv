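SNP	CHR	BP	ALLELE1	ALLELE0	A1FREQ	BETA	SE	P_BOLT_LMM
rs201	1	11008	C	G	0.33	0.012	0.004	0.0027
rs202	3	32100	A	T	0.08	-0.004	0.007	0.57
rs203	7	71022	G	A	0.49	0.021	0.0039	7.7e-8
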