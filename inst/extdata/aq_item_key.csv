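item,subscale,agree_keyed
1,AQ_S,0
2,AQ_D,1
3,AQ_I,0
4,AQ_D,1
5,AQ_A,1
6,AQ_A,1
7,AQ_C,1
8,AQ_I,0
9,AQ_A,1
10,AQ_D,0
11,AQ_S,0
12,AQ_A,1
13,AQ_S,1
14,AQ_I,0
15,AQ_S,0
16,AQ_D,1
17,AQ_C,0
18,AQ_C,1
19,AQ_A,1
20,AQ_I,1
21,AQ_I,1
22,AQ_S,1
23,AQ_A,1
24,AQ_I,0
25,AQ_D,0
26,AQ_C,1
27,AQ_C,0
28,AQ_A,0
29,AQ_A,0
30,AQ_A,0
31,AQ_C,0
32,AQ_D,0
33,AQ_C,1
34,AQ_D,0
35,AQ_C,1
36,AQ_S,0
37,AQ_D,0
38,AQ_C,0
39,AQ_C,1
40,AQ_I,0
41,AQ_I,1
42,AQ_I,1
43,AQ_D,1
44,AQ_S,0
45,AQ_S,1
46,AQ_D,1
47,AQ_S,0
48,AQ_S,0
49,AQ_A,0
50,AQ_I,0
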