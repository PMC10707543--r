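athlete_id,label,sex,tier,body_form,physiological_function,physical_quality,comprehensive
M01,W**,male,elite,0.82,1.09,1.68,3.59
M02,Q**,male,elite,0.79,1.31,2.01,4.11
M03,W**,male,elite,0.64,1.31,1.39,3.34
M04,S**,male,elite,0.83,1.09,1.38,3.30
M05,Y**,male,elite,0.87,1.31,1.26,3.44
M06,J**,male,elite,0.71,0.99,1.12,2.82
F01,X**,female,elite,0.94,1.28,1.85,3.94
F02,X**,female,elite,0.84,1.07,1.54,3.45
F03,X**,female,elite,0.82,1.21,1.44,3.46
F04,K**,female,elite,0.74,1.51,1.03,3.28
F05,S**,female,elite,0.81,0.98,1.32,3.11
M07,S**,male,excellent,0.69,1.09,1.09,2.88
M08,L**,male,excellent,0.70,1.19,1.26,3.15
M09,Y**,male,excellent,0.63,1.19,1.26,3.09
M10,L**,male,excellent,0.75,0.98,0.79,2.52
M11,F**,male,excellent,0.60,1.08,1.13,2.81
M12,S**,male,excellent,0.92,0.76,1.26,2.94
M13,L**,male,excellent,0.70,1.42,1.18,3.29
M14,G**,male,excellent,0.78,0.76,1.26,2.80
M15,L**,male,excellent,0.75,1.09,1.07,2.91
F06,L**,female,excellent,0.93,1.15,1.12,3.19
F07,L**,female,excellent,0.59,0.84,0.91,2.34
F08,J**,female,excellent,0.73,0.64,1.12,2.49
F09,Y**,female,excellent,0.63,0.84,1.23,2.70
F10,D**,female,excellent,0.87,0.96,1.21,3.05
F11,S**,female,excellent,0.81,0.73,1.04,2.58
F12,Z**,female,excellent,1.06,0.62,0.91,2.59
F13,Y**,female,excellent,0.65,1.07,1.23,2.96
F14,L**,female,excellent,0.62,0.77,0.86,2.26
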