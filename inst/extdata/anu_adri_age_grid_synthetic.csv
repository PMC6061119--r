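age_lo,male,female
-Inf,0,0
65,2,5
70,5,11
75,10,18
80,15,26
85,21,34
90,26,41
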