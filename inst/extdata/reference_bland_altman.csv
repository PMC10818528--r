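scenario,n,ba_mean,ba_upper,ba_lower
case_I,1095,1.33,2.32,0.35
case_II,218,1.24,3.11,-0.64
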