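var,sbp,ldl,bmi,bgl
sbp,400,2,16,6
ldl,2,1,0.4,0.3
bmi,16,0.4,16,2.4
bgl,6,0.3,2.4,4
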