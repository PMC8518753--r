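quantity,value,units
chamber_h2_at_20uLmin,4.5,mM
saturation_flow_upper_bound,2,uL/min
optimal_flow_baseline,5.5,uL/min
product_at_20uLmin_upper_bound,0.05,mM
peak_product_h2_40mM,1.2,mM
peak_gain_chamber_upstream,0.5,mM
h2_40mM_over_baseline_ratio_low,1.7,ratio
h2_40mM_over_baseline_ratio_high,2.3,ratio
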