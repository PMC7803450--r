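schema_version: 1
settings:
  cycle_length: 1.0
  max_cycles: 55.0
  discount_rate_costs: 0.035
  discount_rate_qalys: 0.035
  wtp_threshold: 20000.0
  currency_year: 2016/17
profile:
  start_age: 60.0
  sex: male
  r10: 0.1
risk_increment: 0.001
comparator_treatment_delay: never
risk_cap: 0.99
smr_split: excess_to_cvd
adverse:
  annual_probability: 0.02
  background_probability: 0.0
  cost_per_event: 400.0
  disutility: 0.05
smr:
  stable_angina: 1.5
  unstable_angina: 2.0
  mi: 2.5
  stroke: 2.5
  tia: 1.5
  heart_failure: 3.5
costs:
  annual_drug_cost: 25.0
  annual_monitoring_cost: 110.0
tables:
  events: event_distribution.csv
  lifetable: lifetable.csv
  rr: treatment_rr.csv
  baseline_utility: baseline_utility.csv
  multipliers: state_multipliers.csv
  event_costs: event_costs.csv
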