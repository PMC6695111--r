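age,qx
0,0.000217919714491
1,0.000219713668103
2,0.000221687013357
3,0.000223857688639
4,0.000226245426005
5,0.000228871930521
6,0.000231761077519
7,0.000234939129574
8,0.000238434975166
9,0.000242280391199
10,0.000246510331752
11,0.000251163245690
12,0.000256281426010
13,0.000261911394098
14,0.000268104322376
15,0.000274916499173
16,0.000282409840037
17,0.000290652450116
18,0.000299719242709
19,0.000309692619585
20,0.000320663219229
21,0.000332730739785
22,0.000346004844146
23,0.000360606155363
24,0.000376667351371
25,0.000394334368928
26,0.000413767727601
27,0.000435143985778
28,0.000458657341784
29,0.000484521394539
30,0.000512971079580
31,0.000544264797833
32,0.000578686756244
33,0.000616549541226
34,0.000658196947953
35,0.000704007090764
36,0.000754395822417
37,0.000809820492600
38,0.000870784079092
39,0.000937839728138
40,0.001011595744162
41,0.001092721072763
42,0.001181951325125
43,0.001280095396537
44,0.001388042736702
45,0.001506771334896
46,0.001637356488909
47,0.001780980433071
48,0.001938942907537
49,0.002112672758457
50,0.002303740666668
51,0.002513873111177
52,0.002744967682965
53,0.002999109874527
54,0.003278591481111
55,0.003585930760801
56,0.003923894512385
57,0.004295522242334
58,0.004704152605108
59,0.005153452314315
60,0.005647447735849
61,0.006190559387814
62,0.006787639585596
63,0.007444013483532
64,0.008165523776824
65,0.008958579338167
66,0.009830208072339
67,0.010788114277883
68,0.011840740807058
69,0.012997336312105
70,0.014268027856116
71,0.015663899148502
72,0.017197074635972
73,0.018880809637347
74,0.020729586651171
75,0.022759217885069
76,0.024986953950431
77,0.027431598529988
78,0.030113628652577
79,0.033055319991659
80,0.036280876333175
81,0.039816562024405
82,0.043690835807462
83,0.047934483946451
84,0.052580749962533
85,0.057665457581337
86,0.063227122656860
87,0.069307048849457
88,0.075949400687600
89,0.083201246320397
90,0.091112560760693
91,0.099736178722814
92,0.109127684279830
93,0.119345222520650
94,0.130449216213971
95,0.142501968245652
96,0.155567128383378
97,0.169709000875201
98,0.184991667698626
99,0.201477901202625
100,1.000000000000000
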