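patient,interval_days,expected_urgent
p01,0,1
p02,1,1
p03,2,1
p04,3,0
p05,4,0
p06,5,0
p07,2,1
p08,0,1
p09,12,0
p10,7,0
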