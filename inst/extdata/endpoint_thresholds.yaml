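# Diabetes endpoint ascertainment thresholds.
# HbA1c values are on the Swedish Mono-S scale; 6.0% Mono-S corresponds
# to 7.0% NGSP (stored as a correspondence, no conversion formula).
hba1c_monos_min: 6.0
hba1c_min_count: 2
hba1c_ngsp_equivalent: 7.0
fpg_min: 7.0        # fasting plasma glucose, mmol/L (inclusive)
fwbg_min: 6.1       # fasting whole-blood glucose, mmol/L (inclusive)
ogtt_2h_gt: 11.0    # 2-h post-OGTT plasma glucose, mmol/L (strictly >)
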