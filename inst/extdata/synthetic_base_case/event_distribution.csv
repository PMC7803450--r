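age_lo,age_hi,sex,stable_angina,unstable_angina,mi,stroke,tia,heart_failure,fatal_cvd
40,49,male,0.16,0.08,0.3,0.18,0.1,0.06,0.12
50,59,male,0.15,0.08,0.28,0.2,0.11,0.07,0.11
60,69,male,0.14,0.07,0.25,0.24,0.12,0.08,0.1
70,79,male,0.12,0.06,0.22,0.26,0.12,0.1,0.12
80,115,male,0.09,0.05,0.18,0.28,0.12,0.13,0.15
40,49,female,0.18,0.08,0.22,0.22,0.12,0.06,0.12
50,59,female,0.17,0.08,0.21,0.24,0.12,0.07,0.11
60,69,female,0.16,0.07,0.19,0.27,0.13,0.08,0.1
70,79,female,0.13,0.06,0.17,0.29,0.13,0.1,0.12
80,115,female,0.1,0.05,0.14,0.3,0.13,0.13,0.15
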