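"age_Myr","value"
0,11.048
1,12.557
2,12.217
3,12.3
4,13.769
5,13.041
6,14.125
7,13.127
8,13.761
9,14.069
10,14.876
11,15.414
12,15.426
13,15.043
14,15.974
15,15.484
16,15.48
17,17.31
18,16.834
19,16.117
20,18.062
21,16.335
22,17.416
23,18.534
24,17.109
25,18.582
26,18.301
27,20.342
28,17.682
29,19.343
30,20.588
31,19.319
32,20.34
33,20.291
34,21.124
35,19.154
36,23.157
37,19.213
38,20.882
39,20.825
40,21.996
41,23.623
42,21.84
43,21.733
44,22.557
45,22.996
46,23.786
47,24.231
48,24.864
49,24.204
50,25.671
51,24.093
52,24.238
53,24.839
54,26.831
55,25.365
56,24.871
57,26.659
58,25.356
59,26.713
60,27.408
61,27.168
62,26.998
63,28.126
64,26.592
65,28.765
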