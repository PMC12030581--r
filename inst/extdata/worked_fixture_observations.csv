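"sample_id","time_h","release_pct"
1,1,9.85796711332531
1,1.70224,12.5241056106771
1,2.89761,15.9112879119198
1,4.93242,20.2145644132456
1,8.39616,25.6816949289558
1,14.2923,32.6274641096414
1,24.3288,41.4516358916167
1,41.4134,52.6624141556977
1,70.4955,66.9052184169908
1,120,85
2,0.5,11.7503097415405
2,1.85714,37.1415617612691
2,3.21429,55.2273399680539
2,4.57143,68.1093556571208
2,5.92857,77.2849503273124
2,7.28571,83.8205375819609
2,8.64286,88.4757306951962
2,10,91.7915001376101
3,2,13.9483847166804
3,2.84361,17.4847499522432
3,4.04306,21.7979089755145
3,5.74844,26.9888164506534
3,8.17317,33.1305705150592
3,11.6207,40.2407653460588
3,16.5223,48.2458119928136
3,23.4915,56.9436523439296
3,33.4003,65.9742862937354
3,47.4888,74.8221470901399
3,67.5198,82.8724301726943
3,96,89.5375928112148
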