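sample_id,class_label,nihss,hours_to_draw,age,anticoagulant,antihypertensive,hypertension,dyslipidaemia,history_mi,history_afib
S001,control,0,NA,57.3,0,1,0,0,0,0
S002,control,0,NA,67.3,0,0,0,0,0,0
S003,control,0,NA,41.5,0,0,0,0,0,0
S004,control,0,NA,64.4,0,1,1,0,0,0
S005,control,0,NA,61.1,0,1,0,0,0,0
S006,AIS,0,9.64,77.5,0,1,0,0,1,0
S007,AIS,8,3.68,53.5,0,1,0,0,0,0
S008,AIS,0,9.52,83.9,1,1,0,1,1,0
S009,AIS,3,4.73,85.8,0,0,1,1,1,0
S010,AIS,9,4.95,95.4,0,1,0,0,0,0
S011,AIS,0,5.83,58.5,1,0,1,0,1,0
S012,AIS,0,26.42,66.7,0,0,0,0,0,0
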