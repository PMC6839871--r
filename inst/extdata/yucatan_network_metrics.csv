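site,n_plants,n_visitors,h2prime,nodf,modularity,robustness,nestedness_significant
Chapo 1,12,31,0.53,25.80,0.43,0.64,TRUE
Playa Maya,8,35,0.37,33.92,0.34,0.62,TRUE
Chapo 2,14,38,0.61,22.78,0.42,0.64,TRUE
Telchac,14,36,0.35,27.81,0.35,0.68,TRUE
Cancunito,8,22,0.52,36.66,0.36,0.66,TRUE
Punta Meco,14,32,0.40,26.54,0.37,0.66,TRUE
Sisal,11,27,0.29,26.75,0.38,0.62,TRUE
Charcas,11,30,0.65,26.13,0.41,0.66,FALSE
Chabihau,17,28,0.37,27.8,0.36,0.69,TRUE
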