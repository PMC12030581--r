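"sample_id","kp","weibull","mlp"
1,0.786,0.863,0.981
2,0.928,0.976,0.991
3,0.996,0.966,0.994
4,0.967,0.989,0.987
5,0.892,0.963,0.989
6,0.99,0.99,0.994
7,0.924,0.985,0.991
8,0.992,0.994,0.954
9,0.891,0.954,0.995
10,0.949,0.963,0.938
11,0.984,0.993,0.995
12,0.98,0.988,0.977
13,0.952,0.966,0.979
14,0.931,0.948,0.994
15,0.996,0.987,0.994
16,0.914,0.934,0.981
17,0.982,0.997,0.966
18,0.974,0.99,0.955
19,0.996,0.983,0.976
20,0.888,0.99,0.986
21,0.988,0.96,0.995
22,0.993,0.971,0.917
23,0.975,0.964,0.885
24,0.933,0.915,0.961
25,0.981,0.99,0.989
26,0.957,0.987,0.92
27,0.94,0.978,0.994
28,0.961,0.941,0.854
29,0.942,0.994,0.981
30,0.957,0.983,0.988
31,0.988,0.981,0.983
32,0.902,0.956,0.968
33,0.856,0.999,0.983
34,0.991,0.988,0.964
35,0.808,0.943,0.949
36,0.937,0.966,0.982
37,0.843,0.987,0.967
38,0.718,0.973,0.964
39,0.829,0.727,0.967
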