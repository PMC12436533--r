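subject,rater
S1,T1
S1,T2
S1,T3
S2,T1
S2,T2
S2,T3
S3,T1
S3,T2
S3,T3
S4,T1
S4,T2
S4,T3
S5,T1
S5,T2
S5,T3
S6,T1
S6,T2
S6,T3
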