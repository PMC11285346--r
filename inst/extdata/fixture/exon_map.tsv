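gene	node_id	exon_id
G001	1	G001:e1
G001	2	G001:e2
G001	3	G001:e3
G001	4	G001:e4
G001	5	G001:e5
G001	6	G001:e6
G001	7	G001:e7
G002	1	G002:e1
G002	2	G002:e2
G002	3	G002:e3
G002	4	G002:e4
G002	5	G002:e5
G002	6	G002:e6
G002	7	G002:e7
G003	1	G003:e1
G003	2	G003:e2
G003	3	G003:e3
G003	4	G003:e4
G003	5	G003:e5
G003	6	G003:e6
G003	7	G003:e7
G004	1	G004:e1
G004	2	G004:e2
G004	3	G004:e3
G004	4	G004:e4
G004	5	G004:e5
G004	6	G004:e6
G004	7	G004:e7
G005	1	G005:e1
G005	2	G005:e2
G005	3	G005:e3
G005	4	G005:e4
G005	5	G005:e5
G005	6	G005:e6
G006	1	G006:e1
G006	2	G006:e2
G006	3	G006:e3
G006	4	G006:e4
G006	5	G006:e5
G006	6	G006:e6
G006	7	G006:e7
G007	1	G007:e1
G007	2	G007:e2
G007	3	G007:e3
G007	4	G007:e4
G007	5	G007:e5
G007	6	G007:e6
G008	1	G008:e1
G008	2	G008:e2
G008	3	G008:e3
G008	4	G008:e4
G008	5	G008:e5
G008	6	G008:e6
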