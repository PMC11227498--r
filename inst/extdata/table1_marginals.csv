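marker,g0,g1,g2,g3
ck56,146,21,9,14
p63,125,43,14,8
gata6,2,13,60,115
hnf4a,28,31,65,66
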