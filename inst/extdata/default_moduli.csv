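region,WT_mean_kpa,WT_se_kpa,KO_mean_kpa,KO_se_kpa
epidermis,12.04,1.16,4.70,0.36
upper,9.60,0.99,4.73,0.47
middle,6.89,0.46,4.11,0.30
lower,6.46,0.51,5.50,0.58
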