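index,sex,threshold,inequality
achilles_tendon_length,male,22.83,>=
pelvis_width,male,28.76,>=
waist_circumference,male,73.66,>=
quetelet_index,male,424.72,>=
rel_max_anaerobic_power,male,16.78,>=
rel_max_oxygen_uptake,male,50.20,>=
hemoglobin,male,165,>=
power_clean,male,103,>=
squat_balance_pad,male,9.09,<=
sprint_30m,male,3.84,<=
run_12min,male,2939,>=
achilles_tendon_length,female,21.42,>=
pelvis_width,female,27.16,>=
waist_circumference,female,72.71,>=
quetelet_index,female,373.86,>=
rel_max_anaerobic_power,female,14.86,>=
rel_max_oxygen_uptake,female,51.06,>=
hemoglobin,female,142,>=
power_clean,female,64,>=
squat_balance_pad,female,10.04,<=
sprint_30m,female,4.63,<=
run_12min,female,2771,>=
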