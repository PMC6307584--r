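# synthetic example cohort (hand-written, for documentation and quick starts)
patient_id,cohort,t_intervention,t_end,discharged,age,sex
s001,intervention_era,9,31,TRUE,74,female
s002,intervention_era,25,88,TRUE,81,male
s003,intervention_era,50,140,TRUE,69,female
s004,intervention_era,12,12,TRUE,77,male
s005,intervention_era,30,95,FALSE,83,female
s006,intervention_era,,21,TRUE,70,male
s007,control,,35,TRUE,68,female
s008,control,,62,TRUE,59,male
s009,control,,110,TRUE,72,male
s010,control,,24,TRUE,88,female
s011,control,,250,TRUE,64,male
s012,control,,47,FALSE,75,female
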