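10,-5,10
15,0,3
10,-1,10
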