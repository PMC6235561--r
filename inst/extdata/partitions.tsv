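enzyme	condition	fraction_mean	fraction_se
RBC	LC	0.618	0.02
RBC	HC	0.218	0.02
GAP1	LC	0.078	0.01
GAP1	HC	0.110	0.01
GAP3	LC	0.078	0.01
GAP3	HC	0.110	0.01
PRK	LC	0.012	0.005
PRK	HC	0.126	0.01
PGK	LC	0.015	0.005
PGK	HC	0.015	0.005
TPI	LC	0.015	0.005
TPI	HC	0.015	0.005
ALD	LC	0.015	0.005
ALD	HC	0.015	0.005
FBPase	LC	0.015	0.005
FBPase	HC	0.015	0.005
TRK	LC	0.015	0.005
TRK	HC	0.015	0.005
SBPase	LC	0.015	0.005
SBPase	HC	0.015	0.005
RPI	LC	0.015	0.005
RPI	HC	0.015	0.005
RPE	LC	0.015	0.005
RPE	HC	0.015	0.005
PGI	LC	0.015	0.005
PGI	HC	0.015	0.005
MDH	LC	0.015	0.005
MDH	HC	0.015	0.005
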