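age_lo,age_hi,sex,utility
40,49,male,0.89
50,59,male,0.86
60,69,male,0.82
70,79,male,0.78
80,115,male,0.72
40,49,female,0.87
50,59,female,0.84
60,69,female,0.8
70,79,female,0.76
80,115,female,0.69
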