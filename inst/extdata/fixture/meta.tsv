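# predsip synthetic fixture (simulated SIP gradients)
# simulator seed: 20240801
gradient_id	treatment	prey	timepoint
C13_E_coli_24h	C13	E_coli	24
C12_E_coli_24h	C12	E_coli	24
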