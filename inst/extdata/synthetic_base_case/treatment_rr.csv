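event_category,age_lo,age_hi,rr,age_factor
stable_angina,40,49,0.9,0.92
stable_angina,50,59,0.9,0.96
stable_angina,60,69,0.9,1
stable_angina,70,79,0.9,1.04
stable_angina,80,115,0.9,1.08
unstable_angina,40,49,0.88,0.92
unstable_angina,50,59,0.88,0.96
unstable_angina,60,69,0.88,1
unstable_angina,70,79,0.88,1.04
unstable_angina,80,115,0.88,1.08
mi,40,49,0.85,0.92
mi,50,59,0.85,0.96
mi,60,69,0.85,1
mi,70,79,0.85,1.04
mi,80,115,0.85,1.08
stroke,40,49,0.75,0.92
stroke,50,59,0.75,0.96
stroke,60,69,0.75,1
stroke,70,79,0.75,1.04
stroke,80,115,0.75,1.08
tia,40,49,0.78,0.92
tia,50,59,0.78,0.96
tia,60,69,0.78,1
tia,70,79,0.78,1.04
tia,80,115,0.78,1.08
heart_failure,40,49,0.72,0.92
heart_failure,50,59,0.72,0.96
heart_failure,60,69,0.72,1
heart_failure,70,79,0.72,1.04
heart_failure,80,115,0.72,1.08
fatal_cvd,40,49,0.85,0.92
fatal_cvd,50,59,0.85,0.96
fatal_cvd,60,69,0.85,1
fatal_cvd,70,79,0.85,1.04
fatal_cvd,80,115,0.85,1.08
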