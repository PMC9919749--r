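# predsip synthetic fixture (simulated SIP gradients)
# simulator seed: 20240801
taxon	genus	family
ASV001	genus001	family001
ASV002	genus001	family001
ASV003	genus002	family001
ASV004	genus002	family001
ASV005	genus003	family001
ASV006	genus003	family001
ASV007	genus004	family002
ASV008	genus004	family002
ASV009	genus005	family002
ASV010	genus005	family002
ASV011	genus006	family002
ASV012	genus006	family002
ASV_prey_Ec	Escherichia-Shigella	Enterobacteriaceae
ASV_prey_Pp	Pseudomonas	Pseudomonadaceae
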