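parameter,low,high,n_points
cost_ctp,370,570,11
sens_cta,0.95,1.0,11
spec_cta,0.336,0.436,11
sens_ctp,0.864,0.964,11
spec_ctp,0.739,0.839,11
cost_ica,2310,3310,11
cost_ptca,3678,5678,11
pretest_probability,0.40,0.80,11
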