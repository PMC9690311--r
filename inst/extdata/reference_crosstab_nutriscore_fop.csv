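row_category,fop_0,fop_1,fop_2,fop_3,fop_4
A,187,8,1,1,0
B,101,12,4,1,0
C,82,21,17,9,0
D,39,28,36,62,0
E,12,4,9,98,4
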