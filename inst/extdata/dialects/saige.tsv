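CHR	POS	MarkerID	Allele1	Allele2	AF_Allele2	BETA	SE	p.value
4	41008	rs301	T	C	0.21	0.031	0.011	0.0048
9	92210	rs302	G	A	0.44	-0.002	0.009	0.82
11	111533	rs303	C	T	0.05	0.088	0.02	1.1e-5
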