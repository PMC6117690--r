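rxn_id	subsystem	lb	ub	equation
EX_GA3P	exchange	0	10	-> 1 ga3p_c
EX_PYR	exchange	0	10	-> 1 pyr_c
DXS	carotenoid biosynthesis	0	1000	1 ga3p_c + 1 pyr_c -> 1 dxp_p
GGPPS	carotenoid biosynthesis	0	1000	1 dxp_p -> 1 ggpp_p
PSY	carotenoid biosynthesis	0	1000	1 ggpp_p -> 1 phytoene_p
FUCO_SYN	carotenoid biosynthesis	0	1000	1 phytoene_p -> 1 fuco_p
DM_FUCO	exchange	0	1000	1 fuco_p ->
GGDR	porphyrin and chlorophyll metabolism	0	1000	1 ggpp_p -> 1 phypp_p
CHLIDE_SYN	porphyrin and chlorophyll metabolism	0	1000	1 ga3p_c -> 1 chlide_p
CHLG	porphyrin and chlorophyll metabolism	0	1000	1 chlide_p + 1 phypp_p -> 1 chla_p
DM_CHLA	exchange	0	1000	1 chla_p ->
PDH	lipid metabolism	0	1000	1 pyr_c -> 1 accoa_c
FAS	fatty acid elongation	0	1000	1 accoa_c -> 1 fa_c
DM_FA	exchange	0	1000	1 fa_c ->
EX_URA	nucleotide metabolism	0	5	-> 1 ura_c
DM_URA	nucleotide metabolism	0	5	1 ura_c ->
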