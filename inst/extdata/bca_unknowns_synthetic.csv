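sample_id,absorbance,dilution_factor
Cap_CH3OH100_R1,0.154,1
Cap_CH3OH100_R2,0.149,1
Cap_CH3OH50_R1,0.711,2
Cap_CH3OH50_R2,0.742,2
Wha_CH3OH100_R1,0.171,1
Wha_CH3OH50_R1,0.334,2
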