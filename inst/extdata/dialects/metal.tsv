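MarkerName	Allele1	Allele2	Freq1	Effect	StdErr	P-value
rs401	A	G	0.61	0.0088	0.0031	0.0045
rs402	C	T	0.17	-0.0123	0.0058	0.034
rs403	G	A	0.33	0.0005	0.0029	0.86
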