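concentration_ug_ml,absorbance
0,0.052
25,0.075
125,0.168
250,0.281
500,0.512
750,0.744
1000,0.969
1500,1.432
2000,1.891
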