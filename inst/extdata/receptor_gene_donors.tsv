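gene_id	scaffold	length_bp	exons	ga_donors	gg_donors
IR8a	68	33279	33	5	0
IR21a	3	33150	23	4	1
IR25a	269	90005	34	4	2
IR76b	532	18715	19	1	0
IR93a	35	18850	20	0	1
GluR1	77	69907	25	3	0
GluR2	5	24096	23	2	0
NMDAR1	43	63037	36	2	0
NMDAR2-1	101	123322	37	6	1
NMDAR2-2	141	86450	47	4	0
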