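# SpliceIndex markers --cell-type T01
node	gene	cell_type	direction	tp	fp	fn	precision	recall	f1
G003_2	G003	T01	inclusion	2	0	1	1	0.666667	0.8
G001_1	G001	T01	inclusion	0	0	3	0	0.000000	0.0
G001_1	G001	T01	exclusion	0	0	3	0	0.000000	0.0
G001_2	G001	T01	inclusion	0	0	3	0	0.000000	0.0
G001_2	G001	T01	exclusion	0	0	3	0	0.000000	0.0
G001_3	G001	T01	inclusion	0	2	3	0	0.000000	0.0
G001_3	G001	T01	exclusion	0	0	3	0	0.000000	0.0
G001_4	G001	T01	inclusion	0	0	3	0	0.000000	0.0
G001_4	G001	T01	exclusion	0	3	3	0	0.000000	0.0
G001_5	G001	T01	inclusion	0	0	3	0	0.000000	0.0
G001_5	G001	T01	exclusion	0	0	3	0	0.000000	0.0
G001_6	G001	T01	inclusion	0	0	3	0	0.000000	0.0
G001_6	G001	T01	exclusion	0	0	3	0	0.000000	0.0
G001_7	G001	T01	inclusion	0	0	3	0	0.000000	0.0
G001_7	G001	T01	exclusion	0	0	3	0	0.000000	0.0
G002_1	G002	T01	inclusion	0	0	3	0	0.000000	0.0
G002_1	G002	T01	exclusion	0	0	3	0	0.000000	0.0
G002_2	G002	T01	inclusion	0	3	3	0	0.000000	0.0
G002_2	G002	T01	exclusion	0	2	3	0	0.000000	0.0
G002_3	G002	T01	inclusion	0	3	3	0	0.000000	0.0
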