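mode,species,start,end
acid,HLNL,8,12
acid,LNL,14,18
acid,HHMD,20,24
acid,d-HHMD,26,30
base,GG-HLNL,4,8
base,G-HLNL,10,14
base,HLNL,16,20
base,HHMD,24,28
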