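label	reactants	products	kf	kr
K_pump	calcium		5	NA
K_CK1	calcium + CaMKII	calcium + pCaMKII	0.002	NA
K_CK2	pCaMKII + CaMKII	2 pCaMKII	0.10000000000000001	NA
K_PP1	pCaMKII + PP1	CaMKII + PP1	0.050000000000000003	NA
K_pde	cAMP		2	NA
K_gef_on	cAMP + GEF	cAMP + GEFa	0.001	NA
K_gef_off	GEFa	GEF	0.10000000000000001	NA
K_erk_gef	GEFa + ERK	GEFa + ppERK	0.001	NA
K_src_on	Gibg + Src	GibgSrc	0.01	NA
K_src_off	GibgSrc	Gibg + Src	0.10000000000000001	NA
K_erk_src	GibgSrc + ERK	GibgSrc + ppERK	0.001	NA
K_mkp	ppERK	ERK	0.10000000000000001	NA
K_erk_ck	pCaMKII + ERK	pCaMKII + ppERK	0.00050000000000000001	NA
K_gibg_clear	Gibg		0.10000000000000001	NA
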