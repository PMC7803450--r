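event_category,event_multiplier,post_multiplier
stable_angina,0.88,0.91
unstable_angina,0.84,0.9
mi,0.8,0.88
stroke,0.63,0.7
tia,0.9,0.94
heart_failure,0.71,0.78
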