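row_category,fop_0,fop_1,fop_2,fop_3,fop_4
1,143,0,0,0,0
2,69,0,12,8,0
3,78,18,4,9,0
4,131,55,51,154,4
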