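subject,rater
S1,R1
S1,R2
S1,R3
S1,R4
S2,R1
S2,R2
S2,R3
S2,R4
S3,R1
S3,R2
S3,R3
S3,R4
S4,R1
S4,R2
S4,R3
S4,R4
S5,R1
S5,R2
S5,R3
S5,R4
S6,R1
S6,R2
S6,R3
S6,R4
S7,R1
S7,R2
S7,R3
S7,R4
S8,R1
S8,R2
S8,R3
S8,R4
S9,R1
S9,R2
S9,R3
S9,R4
S10,R1
S10,R2
S10,R3
S10,R4
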