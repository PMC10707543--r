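sex,rating,elite,excellent
male,Excellent,2,0
male,Good,3,0
male,Average,0,6
male,Poor,1,2
male,Fail,0,1
female,Excellent,1,0
female,Good,3,0
female,Average,1,6
female,Poor,0,1
female,Fail,0,2
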