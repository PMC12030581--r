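{"sample_id":[1,2,3],"model":["kp","weibull","weibull"],"p1":[0.0985796711332531,4,30],"p2":[0.45,1,0.7],"noise_sd":[0,0,0]}
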