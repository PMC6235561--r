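id	equation	enzyme	kind	compartments
RBC	RuBP + CO2 -> 2 3PGA	RBC	enzymatic	both
PGK	3PGA + ATP <-> BPGA + ADP	PGK	enzymatic	both
GAPDH1	BPGA + NADPH <-> GAP + NADP + Pi	GAP1	enzymatic	both
GAPDH3	BPGA + NADPH <-> GAP + NADP + Pi	GAP3	enzymatic	both
TPI	GAP <-> DHAP	TPI	enzymatic	both
FBA	DHAP + GAP <-> FBP	ALD	enzymatic	both
FBPASE	FBP -> F6P + Pi	FBPase	enzymatic	both
TRK1	F6P + GAP <-> E4P + X5P	TRK	enzymatic	both
SBA	DHAP + E4P <-> SBP	ALD	enzymatic	both
SBPASE	SBP -> S7P + Pi	SBPase	enzymatic	both
TRK2	S7P + GAP <-> R5P + X5P	TRK	enzymatic	both
RPI	R5P <-> Ru5P	RPI	enzymatic	both
RPE	X5P <-> Ru5P	RPE	enzymatic	both
PRK	Ru5P + ATP -> RuBP + ADP	PRK	enzymatic	both
PGI	F6P <-> G6P	PGI	enzymatic	both
MDH	OAA + NADPH <-> MAL + NADP	MDH	enzymatic	both
T_RUBP	RuBP[s] <-> RuBP[p]	-	transport	-
T_3PGA	3PGA[s] <-> 3PGA[p]	-	transport	-
T_BPGA	BPGA[s] <-> BPGA[p]	-	transport	-
T_GAP	GAP[s] <-> GAP[p]	-	transport	-
T_DHAP	DHAP[s] <-> DHAP[p]	-	transport	-
T_FBP	FBP[s] <-> FBP[p]	-	transport	-
T_F6P	F6P[s] <-> F6P[p]	-	transport	-
T_E4P	E4P[s] <-> E4P[p]	-	transport	-
T_X5P	X5P[s] <-> X5P[p]	-	transport	-
T_SBP	SBP[s] <-> SBP[p]	-	transport	-
T_S7P	S7P[s] <-> S7P[p]	-	transport	-
T_R5P	R5P[s] <-> R5P[p]	-	transport	-
T_RU5P	Ru5P[s] <-> Ru5P[p]	-	transport	-
T_G6P	G6P[s] <-> G6P[p]	-	transport	-
T_CO2	CO2[s] <-> CO2[p]	-	transport	-
T_ATP	ATP[s] <-> ATP[p]	-	transport	-
T_ADP	ADP[s] <-> ADP[p]	-	transport	-
T_NADP	NADP[s] <-> NADP[p]	-	transport	-
T_NADPH	NADPH[s] <-> NADPH[p]	-	transport	-
T_PI	Pi[s] <-> Pi[p]	-	transport	-
X_GAP_EXP	GAP[s] -> GAP[c]	-	exchange	-
X_GAP_IMP	GAP[c] -> GAP[s]	-	exchange	-
X_DHAP_EXP	DHAP[s] -> DHAP[c]	-	exchange	-
X_DHAP_IMP	DHAP[c] -> DHAP[s]	-	exchange	-
X_3PGA_EXP	3PGA[s] -> 3PGA[c]	-	exchange	-
X_3PGA_IMP	3PGA[c] -> 3PGA[s]	-	exchange	-
X_PI_EXP	Pi[s] -> Pi[c]	-	exchange	-
X_PI_IMP	Pi[c] -> Pi[s]	-	exchange	-
X_CO2_UPT	CO2[c] -> CO2[s]	-	exchange	-
X_CO2_REL	CO2[s] -> CO2[c]	-	exchange	-
X_ATP_IMP	ATP[c] -> ATP[s]	-	exchange	-
X_ADP_EXP	ADP[s] -> ADP[c]	-	exchange	-
X_OAA_IMP	OAA[c] -> OAA[s]	-	exchange	-
X_OAA_EXP	OAA[s] -> OAA[c]	-	exchange	-
X_MAL_EXP	MAL[s] -> MAL[c]	-	exchange	-
X_MAL_IMP	MAL[c] -> MAL[s]	-	exchange	-
ATPASE	ADP + Pi -> ATP	-	pseudo	stroma
FNR	NADP -> NADPH	-	pseudo	stroma
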