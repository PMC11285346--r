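# SpliceIndex blocks
gene	nodes	node_start	node_end	n_nodes	n_exons	direction	cell_type	k	n	K	N	p_value	fraction	high_confidence
G002	G002_2,G002_3,G002_4	2	4	3	3	above	T03	3	3	3	12	0.00454545	1	TRUE
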