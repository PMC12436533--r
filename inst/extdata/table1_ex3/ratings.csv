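subject,rater,category
S1,R1,1
S1,R1,2
S1,R1,3
S1,R2,1
S1,R2,2
S1,R2,3
S1,R3,1
S1,R3,2
S1,R4,1
S1,R4,2
S2,R1,1
S2,R1,2
S2,R1,3
S2,R2,1
S2,R2,2
S2,R2,3
S2,R3,1
S2,R3,2
S2,R4,1
S2,R4,2
S3,R1,1
S3,R1,2
S3,R1,3
S3,R2,1
S3,R2,2
S3,R2,3
S3,R3,1
S3,R3,2
S3,R4,1
S3,R4,2
S4,R1,1
S4,R1,2
S4,R1,3
S4,R2,1
S4,R2,2
S4,R2,3
S4,R3,1
S4,R3,2
S4,R4,1
S4,R4,2
S5,R1,1
S5,R1,2
S5,R1,3
S5,R2,1
S5,R2,2
S5,R2,3
S5,R3,1
S5,R3,2
S5,R4,1
S5,R4,2
S6,R1,1
S6,R1,2
S6,R1,3
S6,R2,1
S6,R2,2
S6,R2,3
S6,R3,1
S6,R3,2
S6,R4,1
S6,R4,2
S7,R1,1
S7,R1,2
S7,R1,3
S7,R2,1
S7,R2,2
S7,R2,3
S7,R3,1
S7,R3,2
S7,R4,1
S7,R4,2
S8,R1,1
S8,R1,2
S8,R1,3
S8,R2,1
S8,R2,2
S8,R2,3
S8,R3,1
S8,R3,2
S8,R4,1
S8,R4,2
S9,R1,1
S9,R1,2
S9,R1,3
S9,R2,1
S9,R2,2
S9,R2,3
S9,R3,1
S9,R3,2
S9,R4,1
S9,R4,2
S10,R1,1
S10,R1,2
S10,R1,3
S10,R2,1
S10,R2,2
S10,R2,3
S10,R3,1
S10,R3,2
S10,R4,1
S10,R4,2
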