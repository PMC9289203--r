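snp	effect_allele	other_allele	beta	se	pvalue	trait
rs77069344	G	T	0.0062	0.0371	0.868	SVS
rs2070895	A	G	0.0367	0.0278	0.187	SVS
rs247616	T	C	-0.0119	0.0258	0.645	SVS
rs964184	C	G	-0.0071	0.0349	0.838	SVS
rs445925	A	G	-0.0365	0.0413	0.378	SVS
rs141622900	A	G	-0.0793	0.0598	0.185	SVS
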