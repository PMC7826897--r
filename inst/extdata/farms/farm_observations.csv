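"farm_id","standard_length_cm","total_length_cm","body_weight_g","body_condition_factor","tan_mg_l","ammonia_nh3_mg_l","ph","temperature_c","dissolved_oxygen_mg_l","oxygen_saturation_pct"
1,19.5,21.7,132,1.8,0.04,0.001,7.84,16.9,9.57,106
2,19.6,21.7,111,1.5,0.79,0.005,7.5,11.5,11,108
3,11.6,13.5,25.3,1.6,NA,NA,7.61,14.8,5.9,62
4,25,27.6,218,1.4,NA,NA,7.75,7.4,9.2,82
5,25.2,26.1,154,0.96,0.03,0,7.5,23.7,8.5,108
6,28.7,32.4,198,0.84,0.21,0,6.4,22.8,9.1,113
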