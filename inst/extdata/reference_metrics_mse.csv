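"sample_id","kp","weibull","mlp"
1,27.629,17.656,2.459
2,46.751,15.429,6.175
3,3.34,25.584,4.767
4,14.638,4.699,5.708
5,63.628,21.99,6.719
6,5.557,5.647,3.146
7,49.384,9.898,5.586
8,2.746,1.875,15.638
9,47.466,19.981,2.201
10,16.702,12.046,20.248
11,8.957,4.159,3.05
12,2.944,1.832,3.461
13,9.013,6.269,3.987
14,32.36,24.187,2.616
15,1.554,4.597,2.049
16,39.187,29.911,8.516
17,6.631,1.129,12.594
18,26.738,9.755,45.325
19,3.147,12.502,17.529
20,73.67,6.492,9.065
21,8.806,28.458,3.737
22,3.032,13.482,37.949
23,7.718,11.115,35.374
24,26.282,33.064,15.017
25,6.708,3.505,4.098
26,25.273,7.703,46.85
27,30.68,11.166,2.797
28,4.523,6.805,16.989
29,40.652,3.897,13.56
30,29.529,12.047,8.091
31,5.611,8.519,7.5
32,60.37,27.353,19.663
33,104.735,0.918,12.06
34,2.705,3.831,11.066
35,176.78,52.661,46.605
36,20.648,11.06,5.895
37,123.463,10.139,25.502
38,124.397,11.997,15.682
39,54.805,87.494,10.724
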