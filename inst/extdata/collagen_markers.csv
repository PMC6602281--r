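marker_id,collagen_type,chain,sequence,charge,sequence_source
a1I_m1,I,alpha1(I),GETGPAGPAGPIGPVGAR,2,synthetic
a1I_m2,I,alpha1(I),GVPGPPGAVGPAGK,2,synthetic
a2I_m1,I,alpha2(I),GEAGAAGPAGPAGPR,2,synthetic
a2I_m2,I,alpha2(I),GIPGEFGLPGPAGAR,2,synthetic
a1III_m1,III,alpha1(III),GEVGPAGSPGSNGAPGQR,2,synthetic
a1III_m2,III,alpha1(III),GAPGPQGPPGAPGPLGIAGLTGAR,2,synthetic
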