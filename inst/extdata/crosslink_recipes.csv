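name,components,n_water,n_h2,glycan
LNL,Lys-ald;Lys,1,1,
HLNL,Lys-ald;Hyl,1,1,
G-HLNL,Lys-ald;Hyl,1,1,C6H10O5
GG-HLNL,Lys-ald;Hyl,1,1,C12H20O10
HHMD,Lys-ald;Lys-ald;His;Hyl,2,1,
d-HHMD,Lys-ald;Lys-ald;His;Lys,2,1,
ACP,Lys-ald;Lys-ald,1,0,
dehydro-LNL,Lys-ald;Lys,1,0,
dehydro-HLNL,Lys-ald;Hyl,1,0,
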