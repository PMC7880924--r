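{
  "pretest_probability": 0.6267,
  "start_age": 65,
  "wtp": 100000,
  "discount_rate": 0.03,
  "horizon_cycles": 10,
  "sens_cta": 1.0,
  "spec_cta": 0.386,
  "sens_ctp": 0.914,
  "spec_ctp": 0.789,
  "sens_combo": 1.0,
  "spec_combo": 0.429,
  "cost_cta": 397.87,
  "cost_ctp": 470.31,
  "cost_ica": 2810.0,
  "cost_ptca": 4678.0,
  "yearly_cost_no_stenosis": 5837.27,
  "utility_no_stenosis": 0.75,
  "utility_stenosis": 0.70,
  "utility_dead": 0,
  "p_new_stenosis": 0.0264,
  "p_death_stenosis": 0.0230,
  "p_death_no_stenosis": 0.0232,
  "p_death_other": 0.0126,
  "linked_assumption": true
}
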