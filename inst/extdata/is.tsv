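snp	effect_allele	other_allele	beta	se	pvalue	trait
rs77069344	G	T	0.0153	0.0160	0.339	IS
rs2070895	A	G	-0.0033	0.0121	0.783	IS
rs247616	T	C	0.0082	0.0110	0.455	IS
rs964184	C	G	0.0181	0.0152	0.233	IS
rs445925	A	G	-0.0298	0.0184	0.106	IS
rs141622900	A	G	-0.0579	0.0254	0.023	IS
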