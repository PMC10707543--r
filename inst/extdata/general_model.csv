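index,sex,mean,sd
achilles_tendon_length,male,21.94,0.85
pelvis_width,male,26.90,1.55
waist_circumference,male,71.72,2.66
quetelet_index,male,393.99,20.57
rel_max_anaerobic_power,male,14.95,1.43
rel_max_oxygen_uptake,male,52.36,5.04
hemoglobin,male,151.60,7.67
power_clean,male,87.90,19.85
squat_balance_pad,male,11.10,2.19
sprint_30m,male,4.42,0.72
run_12min,male,2644,230.48
achilles_tendon_length,female,20.49,0.71
pelvis_width,female,28.25,5.80
waist_circumference,female,68.77,2.64
quetelet_index,female,347.19,24.79
rel_max_anaerobic_power,female,13.87,0.82
rel_max_oxygen_uptake,female,46.73,4.08
hemoglobin,female,127.14,7.51
power_clean,female,73.43,13.25
squat_balance_pad,female,14.82,4.65
sprint_30m,female,4.98,0.40
run_12min,female,2435,272.53
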