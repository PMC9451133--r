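SNP	CHR	BP	A1	A2	FRQ	OR	SE	P
rs101	1	10177	A	C	0.40	1.05	0.02	0.013
rs102	2	20554	G	T	0.12	0.97	0.031	0.44
rs103	X	30841	T	C	0.25	1.21	0.045	2.3e-5
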