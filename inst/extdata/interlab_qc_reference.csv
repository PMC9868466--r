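quantity,value
ba_mean_bias_pct,9.9
ba_loa_lower_pct,-12.6
ba_loa_upper_pct,32.3
pb_slope,1.09
pb_slope_ci_lower,1.04
pb_slope_ci_upper,1.14
pb_intercept,0.05
pb_intercept_ci_lower,-0.07
pb_intercept_ci_upper,0.19
qc1_nominal,0.64
qc1_between_cv_pct,6.3
qc1_bias_pct,7.7
qc2_nominal,7.5
qc2_between_cv_pct,1.1
qc2_bias_pct,2.6
qc3_nominal,20.9
qc3_between_cv_pct,3.0
qc3_bias_pct,6.6
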