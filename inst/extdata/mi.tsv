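snp	effect_allele	other_allele	beta	se	pvalue	trait
rs77069344	G	T	-0.0651	0.0176	NA	MI
rs2070895	A	G	0.0414	0.0121	0.001	MI
rs247616	T	C	-0.0280	0.0114	0.014	MI
rs964184	C	G	-0.0488	0.0139	NA	MI
rs445925	A	G	-0.0664	0.0214	0.002	MI
rs141622900	A	G	-0.0963	0.0315	0.002	MI
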