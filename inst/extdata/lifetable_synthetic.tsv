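age	qx
0	0.00022997355
1	0.00023279813
2	0.00023588869
3	0.0002392703
4	0.00024297036
5	0.00024701885
6	0.00025144859
7	0.00025629547
8	0.00026159877
9	0.00026740148
10	0.00027375062
11	0.00028069763
12	0.00028829882
13	0.00029661578
14	0.0003057159
15	0.00031567293
16	0.00032656754
17	0.000338488
18	0.00035153091
19	0.00036580192
20	0.00038141667
21	0.00039850164
22	0.00041719524
23	0.0004376489
24	0.00046002828
25	0.00048451466
26	0.00051130634
27	0.00054062027
28	0.00057269385
29	0.00060778675
30	0.00064618309
31	0.00068819368
32	0.00073415857
33	0.00078444975
34	0.00083947416
35	0.00089967699
36	0.00096554521
37	0.0010376116
38	0.0011164587
39	0.0012027242
40	0.0012971051
41	0.001400364
42	0.001513335
43	0.0016369303
44	0.0017721477
45	0.001920078
46	0.0020819144
47	0.0022589617
48	0.0024526462
49	0.0026645277
50	0.0028963115
51	0.0031498616
52	0.0034272158
53	0.0037306012
54	0.0040624519
55	0.0044254277
56	0.004822435
57	0.0052566488
58	0.0057315372
59	0.0062508883
60	0.006818838
61	0.0074399021
62	0.0081190095
63	0.0088615391
64	0.009673359
65	0.01056087
66	0.01153105
67	0.012591506
68	0.013750527
69	0.015017139
70	0.016401169
71	0.017913312
72	0.019565196
73	0.021369462
74	0.02333984
75	0.025491232
76	0.027839801
77	0.03040306
78	0.033199969
79	0.036251033
80	0.039578399
81	0.043205956
82	0.04715944
83	0.051466528
84	0.056156929
85	0.061262478
86	0.066817201
87	0.072857387
88	0.079421619
89	0.086550799
90	0.094288125
91	0.10267904
92	0.11177113
93	0.12161394
94	0.13225878
95	0.14375834
96	0.15616634
97	0.16953695
98	0.18392412
99	0.19938079
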