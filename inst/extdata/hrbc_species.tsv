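# Reduced human red-blood-cell model: 30 metabolites.
# Reconstruction of the standard reduced erythrocyte network (glycolysis +
# pentose phosphate pathway + Rapoport-Leubering shunt + ATPase/NADPHase
# pumps). Concentrations (mol/L) are textbook physiological estimates; the
# five boundary species (GLC, LAC, K, Na, CO2) carry typical blood values.
# u = 0 here: exchange rates of the case study are supplied at run time as
# the three free fluxes.
id	cbar	u	is_boundary
GLC	5.0e-3	0	TRUE
G6P	3.8e-5	0	FALSE
F6P	1.6e-5	0	FALSE
FDP	7.6e-6	0	FALSE
DHAP	1.4e-4	0	FALSE
GAP	5.7e-6	0	FALSE
DPG13	4.0e-7	0	FALSE
DPG23	5.0e-3	0	FALSE
PG3	4.5e-5	0	FALSE
PG2	1.4e-5	0	FALSE
PEP	1.7e-5	0	FALSE
PYR	7.7e-5	0	FALSE
LAC	1.0e-3	0	TRUE
ATP	1.85e-3	0	FALSE
ADP	1.5e-4	0	FALSE
NAD	6.0e-5	0	FALSE
NADH	2.0e-7	0	FALSE
NADP	6.0e-7	0	FALSE
NADPH	6.5e-5	0	FALSE
PI	1.0e-3	0	FALSE
GL6P	2.0e-6	0	FALSE
GO6P	2.5e-5	0	FALSE
RU5P	5.0e-6	0	FALSE
R5P	1.3e-5	0	FALSE
X5P	1.3e-5	0	FALSE
S7P	7.0e-5	0	FALSE
E4P	5.0e-6	0	FALSE
CO2	1.2e-3	0	TRUE
K	4.0e-3	0	TRUE
Na	1.4e-1	0	TRUE
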