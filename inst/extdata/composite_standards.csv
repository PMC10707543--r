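column,sex,p10,p25,p75,p90
body_form,male,0.63,0.69,0.80,0.85
physiological_function,male,0.85,1.03,1.25,1.31
physical_quality,male,1.08,1.13,1.32,1.56
comprehensive,male,2.80,2.85,3.32,3.53
body_form,female,0.62,0.67,0.83,0.91
physiological_function,female,0.67,0.79,1.13,1.26
physical_quality,female,0.91,1.03,1.30,1.51
comprehensive,female,2.39,2.58,3.26,3.46
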