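cell_id	cell_type
T01_c001	T01
T01_c002	T01
T01_c003	T01
T01_c004	T01
T01_c005	T01
T01_c006	T01
T01_c007	T01
T01_c008	T01
T01_c009	T01
T01_c010	T01
T01_c011	T01
T01_c012	T01
T02_c001	T02
T02_c002	T02
T02_c003	T02
T02_c004	T02
T02_c005	T02
T02_c006	T02
T02_c007	T02
T02_c008	T02
T02_c009	T02
T02_c010	T02
T02_c011	T02
T02_c012	T02
T03_c001	T03
T03_c002	T03
T03_c003	T03
T03_c004	T03
T03_c005	T03
T03_c006	T03
T03_c007	T03
T03_c008	T03
T03_c009	T03
T03_c010	T03
T03_c011	T03
T03_c012	T03
T04_c001	T04
T04_c002	T04
T04_c003	T04
T04_c004	T04
T04_c005	T04
T04_c006	T04
T04_c007	T04
T04_c008	T04
T04_c009	T04
T04_c010	T04
T04_c011	T04
T04_c012	T04
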