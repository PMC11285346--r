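# SpliceIndex mxe
gene	node_a	node_b	orientation	cell_type	k	n	K	N	p_value	fraction	delta_psi	adjacent	high_confidence
G001	G001_3	G001_4	a_in_b_out	T02	2	3	2	12	0.0454545	0.666667	0.876014	TRUE	TRUE
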