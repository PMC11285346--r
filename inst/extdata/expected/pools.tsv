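# SpliceIndex pools
pool_id	cell_type	cells	n_cells
T01.1	T01	T01_c012,T01_c010,T01_c006,T01_c005	4
T01.2	T01	T01_c004,T01_c007,T01_c001,T01_c009	4
T01.3	T01	T01_c002,T01_c008,T01_c011,T01_c003	4
T02.1	T02	T02_c010,T02_c006,T02_c004,T02_c008	4
T02.2	T02	T02_c011,T02_c012,T02_c007,T02_c005	4
T02.3	T02	T02_c009,T02_c003,T02_c002,T02_c001	4
T03.1	T03	T03_c010,T03_c005,T03_c002,T03_c008	4
T03.2	T03	T03_c003,T03_c004,T03_c007,T03_c009	4
T03.3	T03	T03_c011,T03_c001,T03_c006,T03_c012	4
T04.1	T04	T04_c004,T04_c008,T04_c010,T04_c002	4
T04.2	T04	T04_c005,T04_c007,T04_c006,T04_c001	4
T04.3	T04	T04_c009,T04_c003,T04_c012,T04_c011	4
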