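metabolite	carbon	phosphate
RuBP	5	2
3PGA	3	1
BPGA	3	2
GAP	3	1
DHAP	3	1
FBP	6	2
F6P	6	1
E4P	4	1
X5P	5	1
SBP	7	2
S7P	7	1
R5P	5	1
Ru5P	5	1
G6P	6	1
OAA	4	0
MAL	4	0
CO2	1	0
ATP	0	3
ADP	0	2
NADP	0	0
NADPH	0	0
Pi	0	1
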