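long,short
A01,A
A09,F
A11,F
A23,Q
A24,Q
A32,f
A62,A62
A76,A76
A92,A92
EixCcBR3,EixCcBR3
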