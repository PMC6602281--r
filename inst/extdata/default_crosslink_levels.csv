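mode,species,WT_mean,WT_sd,Het_mean,Het_sd,KO_mean,KO_sd
acid,HLNL,0.53,0.10,0.47,0.07,0.08,0.01
acid,LNL,0.00,0.00,0.00,0.00,0.09,0.02
acid,HHMD,0.72,0.15,0.75,0.16,0.08,0.03
acid,d-HHMD,0.00,0.00,0.00,0.00,0.28,0.07
base,GG-HLNL,0.18,0.016,0.14,0.016,0.04,0.005
base,G-HLNL,0.10,0.024,0.10,0.020,0.01,0.003
base,HLNL,0.25,0.069,0.23,0.065,0.03,0.006
base,HHMD,0.72,0.15,0.75,0.16,0.08,0.03
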