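subject,rater,category
S1,T1,1
S1,T1,3
S1,T1,4
S1,T2,1
S1,T2,3
S1,T3,1
S1,T3,3
S1,T3,4
S2,T1,1
S3,T1,1
S3,T1,2
S3,T2,1
S3,T2,2
S3,T3,1
S4,T1,1
S4,T1,2
S4,T1,3
S4,T1,4
S4,T2,1
S4,T2,2
S4,T2,3
S4,T2,4
S4,T3,1
S4,T3,2
S4,T3,3
S4,T3,4
S5,T1,1
S5,T1,2
S5,T1,3
S5,T1,4
S5,T1,5
S5,T2,1
S5,T2,2
S5,T2,3
S5,T2,4
S5,T2,5
S5,T3,1
S5,T3,2
S5,T3,3
S5,T3,4
S5,T3,5
S6,T1,1
S6,T1,2
S6,T2,1
S6,T2,2
S6,T3,1
S6,T3,2
S6,T3,3
S6,T3,4
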