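category,score
1,1
2,0
3,1.5
4,0.5
5,-0.5
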