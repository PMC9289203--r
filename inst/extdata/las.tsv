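snp	effect_allele	other_allele	beta	se	pvalue	trait
rs77069344	G	T	0.0450	0.0396	0.256	LAS
rs2070895	A	G	-0.0587	0.0304	0.054	LAS
rs247616	T	C	-0.0168	0.0276	0.542	LAS
rs964184	C	G	0.0060	0.0373	0.872	LAS
rs445925	A	G	-0.0723	0.0461	0.117	LAS
rs141622900	A	G	-0.0963	0.0679	0.156	LAS
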