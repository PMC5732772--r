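snp_id	effect_allele	other_allele	weight
rs1481012	G	A	27.555
rs2231137	A	G	-16.945
rs16890979	T	C	-24.654
rs3799352	T	C	-7.456
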