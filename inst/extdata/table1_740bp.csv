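haplotype,SPSP,Ceara,Bahia,Abrolhos,SouthBrazil
A01,7,20,24,58,17
A09,0,0,2,1,0
A11,0,1,0,0,0
A23,1,0,0,0,0
A24,0,0,0,1,0
A32,0,0,3,2,0
A62,3,1,2,3,5
A76,0,0,1,0,0
A92,1,0,0,0,0
EixCcBR3,0,1,0,0,3
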