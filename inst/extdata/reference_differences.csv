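ga_weeks,period,difference_mg_dl
24,1,0.030
24,2,0.010
24,3,0.006
27,1,0.026
27,2,0.008
27,3,0.005
29,1,0.025
29,2,0.007
29,3,0.005
32,1,0.023
32,2,0.006
32,3,0.004
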