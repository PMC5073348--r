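"displacement","probability"
0,0
1,0.5
2,0
3,0
4,0
5,0
6,0.5
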