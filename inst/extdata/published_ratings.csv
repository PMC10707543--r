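athlete_id,sex,tier,body_form,physiological_function,physical_quality,comprehensive
M01,male,elite,Good,Average,Excellent,Excellent
M02,male,elite,Excellent,Excellent,Excellent,Excellent
M03,male,elite,Poor,Good,Good,Good
M04,male,elite,Good,Average,Good,Good
M05,male,elite,Excellent,Good,Good,Good
M06,male,elite,Good,Poor,Poor,Poor
F01,female,elite,Excellent,Excellent,Excellent,Excellent
F02,female,elite,Good,Average,Good,Good
F03,female,elite,Average,Good,Good,Good
F04,female,elite,Average,Good,Average,Good
F05,female,elite,Good,Average,Good,Average
M07,male,excellent,Average,Average,Poor,Average
M08,male,excellent,Average,Average,Average,Average
M09,male,excellent,Poor,Average,Average,Average
M10,male,excellent,Average,Poor,Fail,Fail
M11,male,excellent,Fail,Average,Average,Poor
M12,male,excellent,Excellent,Fail,Average,Average
M13,male,excellent,Average,Excellent,Average,Average
M14,male,excellent,Average,Fail,Average,Poor
M15,male,excellent,Average,Average,Poor,Average
F06,female,excellent,Excellent,Good,Average,Average
F07,female,excellent,Fail,Average,Poor,Fail
F08,female,excellent,Average,Fail,Average,Poor
F09,female,excellent,Poor,Average,Average,Average
F10,female,excellent,Good,Average,Average,Average
F11,female,excellent,Average,Poor,Average,Average
F12,female,excellent,Excellent,Fail,Poor,Average
F13,female,excellent,Poor,Average,Average,Average
F14,female,excellent,Poor,Poor,Fail,Fail
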