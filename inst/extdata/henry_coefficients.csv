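sex,age_min,age_max,slope_mj_per_kg,intercept_mj
male,18,30,0.0669,2.28
male,30,60,0.0592,2.48
male,60,70,0.0563,2.15
male,70,200,0.0563,2.15
female,18,30,0.0546,2.33
female,30,60,0.0407,2.90
female,60,70,0.0429,2.39
female,70,200,0.0417,2.41
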