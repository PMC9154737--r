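food_group,max_daily_amount,unit
eggs,9,eggs/day
porridge,1100,g/day
bread,800,g/day
milk,3000,ml/day
cheese,500,g/day
red meat,750,g/day
orange juice,2000,ml/day
nuts,400,g/day
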