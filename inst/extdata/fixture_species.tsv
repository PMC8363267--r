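name	initial_nM	role
calcium	0	input
CaMKII	100	kinase
pCaMKII	0	kinase
PP1	20	phosphatase
cAMP	0	input
GEF	100	gef
GEFa	0	gef
Gibg	0	input
Src	100	kinase
GibgSrc	0	kinase
ERK	200	kinase
ppERK	0	kinase
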