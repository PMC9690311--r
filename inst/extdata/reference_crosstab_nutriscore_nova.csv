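row_category,nova_1,nova_2,nova_3,nova_4
A,107,3,50,37
B,17,3,15,83
C,7,39,16,67
D,4,40,25,96
E,8,4,3,112
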