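reaction	keq	delta_n	note
RBC	8.3e4	0	carboxylation of RuBP, apparent Keq at pH 7.5, I 0.1 M
PGK	4.0e-4	0	3PGA phosphorylation by ATP, endergonic as written
GAPDH1	1.3e1	1	BPGA reduction releasing Pi, Keq on mol/L basis
GAPDH3	1.3e1	1	same chemistry as GAPDH1, second chloroplast isoform
TPI	2.2e1	0	GAP to DHAP isomerisation
FBA	1.0e4	-1	aldol condensation DHAP+GAP to FBP, association constant 1/M
FBPASE	8.0e2	1	FBP hydrolysis releasing Pi
TRK1	1.0e-1	0	transketolase F6P+GAP to E4P+X5P
SBA	1.1e4	-1	aldol condensation DHAP+E4P to SBP
SBPASE	3.5e2	1	SBP hydrolysis releasing Pi
TRK2	8.5e-1	0	transketolase S7P+GAP to R5P+X5P
RPI	3.0e-1	0	R5P to Ru5P isomerisation
RPE	6.7e-1	0	X5P to Ru5P epimerisation
PRK	6.8e3	0	Ru5P phosphorylation by ATP
PGI	3.3e0	0	F6P to G6P isomerisation
MDH	2.8e4	0	OAA reduction by NADPH (malate valve)
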