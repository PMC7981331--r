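sex,age_lo,age_hi,dimension,p75
F,18,39,general_fatigue,12
F,18,39,physical_fatigue,11
F,18,39,mental_fatigue,11
F,18,39,reduced_activity,11
F,18,39,reduced_motivation,10
F,40,59,general_fatigue,13
F,40,59,physical_fatigue,12
F,40,59,mental_fatigue,11
F,40,59,reduced_activity,12
F,40,59,reduced_motivation,10
F,60,99,general_fatigue,14
F,60,99,physical_fatigue,13
F,60,99,mental_fatigue,12
F,60,99,reduced_activity,13
F,60,99,reduced_motivation,11
M,18,39,general_fatigue,11
M,18,39,physical_fatigue,10
M,18,39,mental_fatigue,11
M,18,39,reduced_activity,10
M,18,39,reduced_motivation,10
M,40,59,general_fatigue,12
M,40,59,physical_fatigue,11
M,40,59,mental_fatigue,11
M,40,59,reduced_activity,11
M,40,59,reduced_motivation,10
M,60,99,general_fatigue,13
M,60,99,physical_fatigue,12
M,60,99,mental_fatigue,11
M,60,99,reduced_activity,12
M,60,99,reduced_motivation,11
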