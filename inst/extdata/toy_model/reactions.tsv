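id	name	stoichiometry	lb	ub	subsystem	gpr	kind	objective
EX_glc	glucose exchange	-1 glc[e]	-10	0	Exchange		exchange	FALSE
EX_o2	oxygen exchange	-1 o2[e]	-1000	0	Exchange		exchange	FALSE
T_glc1	glucose uptake (outer)	-1 glc[e] + 1 glc[p]	0	1000	Transport	g_t1	transport	FALSE
T_glc2	glucose uptake (inner)	-1 glc[p] + 1 glc[c]	0	1000	Transport	g_t2	transport	FALSE
T_o2	oxygen diffusion	-1 o2[e] + 1 o2[c]	0	1000	Transport		transport	FALSE
ROUTE1	glucose catabolism route 1	-1 glc[c] + -1 adp[c] + -2 nad[c] + 2 pyr[c] + 1 atp[c] + 2 nadh[c]	0	1000	Glycolysis	g_r1a and g_r1b	metabolic	FALSE
ROUTE2	glucose catabolism route 2	-1 glc[c] + -2 adp[c] + -1 nad[c] + 2 pyr[c] + 2 atp[c] + 1 nadh[c]	0	1000	Glycolysis	g_r2a or g_r2b	metabolic	FALSE
TCA	pyruvate oxidation loop	-1 pyr[c] + -4 nad[c] + 3 co2[c] + 4 nadh[c]	0	1000	TCA cycle	g_tca	metabolic	FALSE
T_co2	CO2 diffusion	-1 co2[c] + 1 co2[e]	0	1000	Transport		transport	FALSE
EX_co2	CO2 exchange	-1 co2[e]	0	1000	Exchange		exchange	FALSE
OXPHOS	oxidative phosphorylation	-1.0 nadh[c] + -0.5 o2[c] + -2.0 adp[c] + 1.0 nad[c] + 2.0 atp[c]	0	1000	Oxidative phosphorylation	g_ox	metabolic	FALSE
NOX	uncoupled NADH oxidase	-1.0 nadh[c] + -0.5 o2[c] + 1.0 nad[c]	0	1000	Oxidative phosphorylation		metabolic	FALSE
ESYN	osmolyte synthesis	-1 pyr[c] + -1 atp[c] + 1 ect[c] + 1 adp[c]	0	1000	Compatible solutes	g_es1 and g_es2	metabolic	FALSE
EDEG	osmolyte degradation	-1 ect[c] + 1 pyr[c]	0	1000	Compatible solutes	g_deg	metabolic	FALSE
ATPM	ATP maintenance	-1 atp[c] + 1 adp[c]	7.6	1000	Maintenance		maintenance	FALSE
BIO_L	biomass (low salinity)	-10.0 pyr[c] + -20.0 atp[c] + -0.1 ect[c] + 20.0 adp[c]	0	1000	Biomass		biomass	TRUE
BIO_H	biomass (high salinity)	-10.0 pyr[c] + -20.0 atp[c] + -0.5 ect[c] + 20.0 adp[c]	0	1000	Biomass		biomass	FALSE
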