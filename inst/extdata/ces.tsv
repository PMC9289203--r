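snp	effect_allele	other_allele	beta	se	pvalue	trait
rs77069344	G	T	0.0207	0.0316	0.514	CES
rs2070895	A	G	0.0136	0.0235	0.563	CES
rs247616	T	C	0.0108	0.0212	0.609	CES
rs964184	C	G	0.0122	0.0297	0.681	CES
rs445925	A	G	-0.0362	0.0350	0.301	CES
rs141622900	A	G	0.0178	0.0509	0.727	CES
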