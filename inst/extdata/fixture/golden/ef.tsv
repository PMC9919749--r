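# predsip enrichment-factor table
# config_hash: 15b767ec
# seed: 20240801
taxon	level	prey	timepoint	r13H	r13L	r12H	r12L	ef	passed_filter	labeled	status
ASV003	ASV	E_coli	24	0.678375685102	0.0954160438465	0.204035874439	0.209516691579	6.13581990854	TRUE	TRUE	ok
ASV007	ASV	E_coli	24	0.155206776283	0.0196811160937	0.0396113602392	0.048081714001	7.06224175248	TRUE	TRUE	ok
ASV011	ASV	E_coli	24	0.133781763827	0.00124564025909	0.026158445441	0.0281514698555	 106.47079646	TRUE	TRUE	ok
ASV_prey_Ec	ASV	E_coli	24	0.0301444942701	0.000249128051819	0.00174389636273	0.00174389636273	          120	TRUE	TRUE	ok
Escherichia-Shigella	genus	E_coli	24	0.0301896207585	0.000249500998004	0.00174650698603	0.00174650698603	          120	TRUE	TRUE	ok
genus002	genus	E_coli	24	0.679391217565	0.180389221557	0.28118762475	0.27619760479	2.74818488157	TRUE	TRUE	ok
genus004	genus	E_coli	24	0.155439121756	0.15494011976	0.158932135729	0.167914171657	0.0567124395537	TRUE	FALSE	ok
genus006	genus	E_coli	24	0.133982035928	0.00673652694611	0.0301896207585	0.0326846307385	18.9652247668	TRUE	TRUE	ok
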