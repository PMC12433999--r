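attrition_rate,model,theta_per_1000,lcb,ucb
0.00,three_level,9.15,7.11,11.20
0.00,site_household,9.63,7.68,11.58
0.10,three_level,8.35,6.01,10.69
0.20,three_level,7.67,4.18,11.16
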