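# predsip synthetic fixture (simulated SIP gradients)
# simulator seed: 20240801
gradient_id	fraction_index	density	copies
C13_E_coli_24h	1	1.784615385	185920.4173
C13_E_coli_24h	2	1.793846154	3714003.275
C13_E_coli_24h	3	1.803076923	15268279.63
C13_E_coli_24h	4	1.812307692	46842456.56
C13_E_coli_24h	5	1.821538462	13211723.57
C13_E_coli_24h	6	1.830769231	 2931141.59
C13_E_coli_24h	7	       1.84	1733697.409
C13_E_coli_24h	8	1.849230769	5492813.176
C13_E_coli_24h	9	1.858461538	 9413421.79
C13_E_coli_24h	10	1.867692308	3083503.003
C13_E_coli_24h	11	1.876923077	357243.9592
C13_E_coli_24h	12	1.886153846	15020.71166
C13_E_coli_24h	13	1.895384615	98.00268794
C12_E_coli_24h	1	1.784615385	214305.9832
C12_E_coli_24h	2	1.793846154	3436662.624
C12_E_coli_24h	3	1.803076923	27765592.72
C12_E_coli_24h	4	1.812307692	42371362.82
C12_E_coli_24h	5	1.821538462	24564756.59
C12_E_coli_24h	6	1.830769231	3313351.068
C12_E_coli_24h	7	       1.84	157507.9112
C12_E_coli_24h	8	1.849230769	 1905.10784
C12_E_coli_24h	9	1.858461538	7.564973501
C12_E_coli_24h	10	1.867692308	0.008659829725
C12_E_coli_24h	11	1.876923077	2.445006497e-06
C12_E_coli_24h	12	1.886153846	1.777945727e-10
C12_E_coli_24h	13	1.895384615	3.668878449e-15
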