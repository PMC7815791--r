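age,qx
0,0.000529859574809555
1,0.000532781873364363
2,0.000535988974373347
3,0.000539508633167429
4,0.000543371309749685
5,0.000547610432312662
6,0.000552262686422944
7,0.000557368332367636
8,0.000562971553406899
9,0.000569120837936476
10,0.000575869398861117
11,0.000583275633796676
12,0.000591403630072818
13,0.000600323718889628
14,0.00061011308340897
15,0.000620856426018612
16,0.000632646700519546
17,0.000645585915540092
18,0.000659786016093178
19,0.000675369850858143
20,0.000692472233503994
21,0.00071124110717169
22,0.000731838822112252
23,0.000754443537440808
24,0.000779250759019856
25,0.000806475026639331
26,0.000836351764924803
27,0.000869139313786294
28,0.000905121155731159
29,0.000944608359018995
30,0.00098794225744292
31,0.00103549738949293
32,0.00108768472181908
33,0.00114495518425783
34,0.00120780354626082
35,0.0012767726673566
36,0.00135245815733465
37,0.00143551348515514
38,0.00152665557920362
39,0.00162667096543967
40,0.00173642249424411
41,0.00185685671140101
42,0.00198901193365164
43,0.00213402709467436
44,0.00229315143319186
45,0.00246775510120167
46,0.00265934077710739
47,0.00286955637578645
48,0.00310020895541052
49,0.00335327992912005
50,0.00363094169846434
51,0.00393557583483328
52,0.00426979294491658
53,0.00463645436648907
54,0.0050386958514802
55,0.00547995340427021
56,0.00596399145434456
57,0.00649493355368758
58,0.00707729580040872
59,0.00771602320081632
60,0.00841652919215852
61,0.00918473855713076
62,0.0100271339684905
63,0.010950806407083
64,0.0119635096984836
65,0.0130737194113388
66,0.0142906963531539
67,0.0156245548853213
68,0.0170863362568708
69,0.0186880871236962
70,0.0204429433743908
71,0.0223652193223827
72,0.0244705022433058
73,0.0267757521324025
74,0.029299406424431
75,0.0320614892524995
76,0.0350837246160476
77,0.0383896525745135
78,0.0420047472737546
79,0.0459565352376952
80,0.0502747119076845
81,0.0549912538754476
82,0.0601405236204037
83,0.0657593628162142
84,0.0718871694024912
85,0.0785659526142979
86,0.0858403590149249
87,0.0937576612803089
88,0.102367700035568
89,0.111722767452572
90,0.121877419600641
91,0.132888202734272
92,0.144813276857042
93,0.157711918101383
94,0.171643879826585
95,0.18666859102213
96,0.2028441698229
97,0.220226229971898
98,0.238866459250439
99,0.258810951658222
100,1
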