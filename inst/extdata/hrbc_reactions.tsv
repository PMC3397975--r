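# Reduced human red-blood-cell model: 21 reactions + 2 ionic pumps.
# Glycolysis (HK..LDH), Rapoport-Leubering shunt (DPGM, DPGASE), oxidative +
# non-oxidative pentose phosphate pathway (G6PDH..TKII), Na/K-ATPase and
# NADPHase (glutathione reductase, abstracted). Water and protons are omitted,
# as usual in reduced stoichiometric models. In the ATPase row the K and Na
# species denote the extracellular-facing ion pools, so per ATP the pump
# imports 2 K (consumed from the pool) and exports 3 Na (returned to it).
id	formula	qmax
HK	GLC + ATP -> G6P + ADP	1e-3
PGI	G6P -> F6P	1e-3
PFK	F6P + ATP -> FDP + ADP	1e-3
ALD	FDP -> DHAP + GAP	1e-3
TPI	DHAP -> GAP	1e-3
GAPDH	GAP + NAD + PI -> DPG13 + NADH	1e-3
PGK	DPG13 + ADP -> PG3 + ATP	1e-3
DPGM	DPG13 -> DPG23	1e-3
DPGASE	DPG23 -> PG3 + PI	1e-3
PGM	PG3 -> PG2	1e-3
EN	PG2 -> PEP	1e-3
PK	PEP + ADP -> PYR + ATP	1e-3
LDH	PYR + NADH -> LAC + NAD	1e-3
G6PDH	G6P + NADP -> GL6P + NADPH	1e-3
PGLASE	GL6P -> GO6P	1e-3
GO6PDH	GO6P + NADP -> RU5P + NADPH + CO2	1e-3
R5PI	RU5P -> R5P	1e-3
RPE	RU5P -> X5P	1e-3
TKI	R5P + X5P -> S7P + GAP	1e-3
TA	S7P + GAP -> E4P + F6P	1e-3
TKII	X5P + E4P -> F6P + GAP	1e-3
ATPASE	ATP + 2 K -> ADP + PI + 3 Na	1e-3
NADPHASE	NADPH -> NADP	1e-3
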