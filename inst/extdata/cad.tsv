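snp	effect_allele	other_allele	beta	se	pvalue	trait
rs77069344	G	T	-0.0514	0.0158	0.001	CAD
rs2070895	A	G	0.0372	0.0108	0.001	CAD
rs247616	T	C	-0.0312	0.0103	0.002	CAD
rs964184	C	G	-0.0500	0.0124	NA	CAD
rs445925	A	G	-0.0858	0.0187	NA	CAD
rs141622900	A	G	-0.1421	0.0278	NA	CAD
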