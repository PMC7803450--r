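event_category,event_year_cost,post_event_annual_cost
stable_angina,2700,300
unstable_angina,3300,300
mi,4000,250
stroke,11900,2500
tia,1500,100
heart_failure,5700,1500
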