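scenario,group,n,bias,relative_bias_pct,precision,accuracy
case_I,overall,1095,0.32,37.65,0.01,0.010
case_I,ester_phosphate,81,0.15,15.70,0.05,0.050
case_I,carbamate,24,0.16,17.51,0.01,0.050
case_I,thiophosphate,990,0.01,1.24,0.01,0.004
case_II,overall,218,0.65,91.94,0.06,0.050
case_II,ester_phosphate,39,0.36,43.18,0.15,0.150
case_II,carbamate,18,0.23,25.26,0.03,0.080
case_II,thiophosphate,161,0.07,7.02,0.02,0.020
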