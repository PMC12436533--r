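subject,rater
1,R1
1,R2
1,R3
1,R4
2,R1
2,R2
2,R3
2,R4
3,R1
3,R2
3,R3
3,R4
4,R1
4,R2
4,R3
5,R1
5,R2
5,R3
6,R1
6,R2
6,R3
7,R1
7,R2
7,R3
8,R1
8,R2
8,R3
9,R1
9,R2
9,R3
10,R1
10,R2
10,R3
11,R1
11,R2
11,R3
12,R1
12,R2
12,R3
13,R1
13,R2
13,R3
14,R1
14,R2
14,R3
15,R1
15,R2
15,R3
16,R1
16,R2
16,R3
17,R1
17,R2
17,R3
18,R1
18,R2
18,R3
19,R1
19,R2
19,R3
20,R1
20,R2
20,R3
21,R1
21,R2
21,R3
22,R1
22,R2
22,R3
22,R4
23,R1
23,R2
23,R3
23,R4
24,R1
24,R2
24,R3
24,R4
25,R1
25,R2
25,R3
25,R4
26,R1
26,R2
26,R3
26,R4
27,R1
27,R2
27,R3
27,R4
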