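enzyme	k_lit	k_min	k_max	source
RBC	3.5	0.5	12	literature
PGK	250	1	1000	literature
TPI	4000	10	9000	literature
FBPase	25	0.5	100	literature
SBPase	30	0.5	100	literature
PRK	220	1	900	literature
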