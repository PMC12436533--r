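subject,rater,rank,category
1,R1,1,9
1,R1,2,11
1,R2,1,11
1,R2,2,9
1,R2,3,14
1,R3,1,16
1,R3,2,9
1,R4,1,11
1,R4,2,9
2,R1,1,16
2,R2,1,16
2,R2,2,14
2,R3,1,12
2,R4,1,14
2,R4,2,5
3,R1,1,17
3,R2,1,12
3,R3,1,7
3,R3,2,8
3,R4,1,13
4,R1,1,16
4,R1,2,13
4,R2,1,13
4,R2,2,16
4,R2,3,14
4,R3,1,16
5,R1,1,7
5,R2,1,7
5,R2,2,12
5,R2,3,13
5,R3,1,13
6,R1,1,10
6,R2,1,10
6,R3,1,10
7,R1,1,7
7,R1,2,16
7,R2,1,13
7,R3,1,16
8,R1,1,1
8,R1,2,14
8,R2,1,13
8,R3,1,16
8,R3,2,13
9,R1,1,5
9,R2,1,20
9,R3,1,13
9,R3,2,14
10,R1,1,12
10,R1,2,13
10,R1,3,14
10,R2,1,12
10,R2,2,14
10,R2,3,13
10,R3,1,12
10,R3,2,11
10,R3,3,14
11,R1,1,13
11,R2,1,18
11,R3,1,16
12,R1,1,5
12,R1,2,18
12,R2,1,1
12,R2,2,5
12,R2,3,18
12,R3,1,1
13,R1,1,14
13,R1,2,13
13,R2,1,14
13,R2,2,7
13,R3,1,14
13,R3,2,16
14,R1,1,11
14,R1,2,16
14,R2,1,14
14,R2,2,11
14,R2,3,16
14,R3,1,11
14,R3,2,13
15,R1,1,10
15,R2,1,3
15,R2,2,18
15,R3,1,10
15,R3,2,11
16,R1,1,14
16,R1,2,5
16,R2,1,5
16,R2,2,16
16,R3,1,14
17,R1,1,12
17,R2,1,12
17,R2,2,11
17,R3,1,12
18,R1,1,20
18,R2,1,16
18,R3,1,16
19,R1,1,13
19,R2,1,14
19,R3,1,14
20,R1,1,9
20,R1,2,14
20,R1,3,10
20,R2,1,9
20,R2,2,11
20,R2,3,14
20,R3,1,10
20,R3,2,9
21,R1,1,12
21,R1,2,11
21,R2,1,11
21,R2,2,14
21,R3,1,11
22,R1,1,17
22,R2,1,12
22,R3,1,12
22,R4,1,12
22,R4,2,17
22,R4,3,15
23,R1,1,16
23,R1,2,13
23,R2,1,12
23,R3,1,14
23,R4,1,13
24,R1,1,12
24,R2,1,12
24,R3,1,16
24,R4,1,12
25,R1,1,13
25,R2,1,20
25,R3,1,13
25,R4,1,13
26,R1,1,13
26,R2,1,13
26,R2,2,16
26,R3,1,13
26,R4,1,16
27,R1,1,10
27,R1,2,9
27,R2,1,9
27,R2,2,10
27,R3,1,9
27,R4,1,9
27,R4,2,10
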