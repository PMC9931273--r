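variable,level,lower,upper,points
ed_visits,<1,-Inf,1,0
ed_visits,"[1, 3)",1,3,14
ed_visits,>=3,3,Inf,33
metastatic_cancer,No,NA,NA,0
metastatic_cancer,Yes,NA,NA,21
age,<25,-Inf,25,0
age,"[25, 45)",25,45,4
age,"[45, 75)",45,75,12
age,"[75, 85)",75,85,15
age,>=85,85,Inf,19
sodium,<125,-Inf,125,10
sodium,"[125, 130)",125,130,7
sodium,"[130, 135)",130,135,4
sodium,>=135,135,Inf,0
renal_disease,No,NA,NA,0
renal_disease,Yes,NA,NA,8
ed_triage,P1,NA,NA,9
ed_triage,P2,NA,NA,6
ed_triage,P3 and P4,NA,NA,0
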