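index,sex,direction,units,p10,p25,p75,p90
achilles_tendon_length,male,high_optimal,cm,20.81,21.41,22.44,22.83
pelvis_width,male,high_optimal,cm,25.48,25.90,27.31,28.76
waist_circumference,male,high_optimal,cm,68.78,70.99,73.28,73.66
quetelet_index,male,high_optimal,g/cm,374.28,376.33,406.86,424.72
rel_max_anaerobic_power,male,high_optimal,W/kg,13.53,14.02,15.94,16.78
rel_max_oxygen_uptake,male,high_optimal,ml/kg/min,38.74,40.72,48,50.20
hemoglobin,male,high_optimal,g/L,129,140,160,165
power_clean,male,high_optimal,kg,75,80,98,103
squat_balance_pad,male,low_optimal,s,9.09,9.61,11.50,14.09
sprint_30m,male,low_optimal,s,3.84,4.02,4.58,5.12
run_12min,male,high_optimal,m,2346,2475,2805,2939
achilles_tendon_length,female,high_optimal,cm,19.64,19.94,20.95,21.42
pelvis_width,female,high_optimal,cm,25.43,25.52,26.68,27.16
waist_circumference,female,high_optimal,cm,66.29,66.60,69.45,72.71
quetelet_index,female,high_optimal,g/cm,322.13,331.98,352.42,373.86
rel_max_anaerobic_power,female,high_optimal,W/kg,13.07,13.41,14.34,14.86
rel_max_oxygen_uptake,female,high_optimal,ml/kg/min,41.95,45.37,49.78,51.06
hemoglobin,female,high_optimal,g/L,117,121,137,142
power_clean,female,high_optimal,kg,29,33,52,64
squat_balance_pad,female,low_optimal,s,10.04,11.20,17.96,20.49
sprint_30m,female,low_optimal,s,4.63,4.72,5.15,5.50
run_12min,female,high_optimal,m,2062,2213,2620,2771
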