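chain,label,sequence,pyro_glu,mod_positions,allowed_states,hyp_positions,sequence_source
alpha1(I),Lys-87,GLPGAKGEAGAR,FALSE,6,Lys;Hyl;G-Hyl;GG-Hyl,3,synthetic
alpha1(I),Lys-99,GVQGPKGDAGAR,FALSE,6,Lys;Hyl;G-Hyl;GG-Hyl,5,synthetic
alpha1(I),Lys-174,GEAGSKGDTGAR,FALSE,6,Lys;Hyl;G-Hyl;GG-Hyl,,synthetic
alpha1(I),Lys-219,GPAGEKGSVGAR,FALSE,6,Lys;Hyl,,synthetic
alpha1(I),Lys-564,GDAGPKGDNGAR,FALSE,6,Lys;Hyl;G-Hyl;GG-Hyl,5,synthetic
alpha1(I),Lys-603,GAAGLKGDVGAR,FALSE,6,Lys;Hyl;G-Hyl;GG-Hyl,,synthetic
alpha2(I),Lys-87,GFPGSKGEAGAR,FALSE,6,Lys;Hyl,3,synthetic
alpha2(I),Lys-174,GEVGAKGDSGSR,FALSE,6,Lys;Hyl;G-Hyl;GG-Hyl,,synthetic
alpha2(I),Lys-219,GPSGDKGEAGTR,FALSE,6,Lys;Hyl;G-Hyl;GG-Hyl,,synthetic
alpha2(I),Lys-933,GDQGPKGEPGSR,FALSE,6,Lys;Hyl;G-Hyl;GG-Hyl,9,synthetic
alpha1(I),Lys-918/930,GDKGETGEQGDRGIKGHR,FALSE,3;15,Lys;Hyl,,printed
alpha1(I),Lys-9N,QLSYGYDEKSTGISVP,TRUE,9,Lys;Lys-ald;Hyl,,synthetic
alpha1(I),Lys-16C,SAGFDFSFLPQPPQEKAHDGGR,FALSE,16,Lys;Lys-ald;Hyl,,synthetic
alpha2(I),Lys-5N,QYSDKGVSSGPGPM,TRUE,5,Lys;Lys-ald;Hyl,,printed
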