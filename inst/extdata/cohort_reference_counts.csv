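variable,category,n_total,n_excessive,reference,crude_or,crude_ci_low,crude_ci_high,adj_or,adj_ci_low,adj_ci_high
sex,Boys,166,37,TRUE,1,NA,NA,1,NA,NA
sex,Girls,166,35,FALSE,0.93,0.55,1.57,0.91,0.49,1.67
age,3,87,23,TRUE,1,NA,NA,1,NA,NA
age,4,86,17,FALSE,0.69,0.34,1.40,0.61,0.27,1.38
age,5,85,18,FALSE,0.75,0.37,1.51,0.43,0.18,1.04
age,6,74,14,FALSE,0.65,0.31,1.38,0.36,0.13,0.94
weight_status,Normal,269,59,TRUE,1,NA,NA,1,NA,NA
weight_status,Underweight,35,8,FALSE,1.06,0.46,2.44,0.83,0.31,2.19
weight_status,Overweight and obese,28,5,FALSE,0.78,0.28,2.12,0.86,0.27,2.72
sleep,<10,52,15,TRUE,1,NA,NA,1,NA,NA
sleep,>=10,280,57,FALSE,0.63,0.32,1.23,0.41,0.18,0.94
outdoor,<1,85,21,TRUE,1,NA,NA,1,NA,NA
outdoor,>=1 to <2,158,36,FALSE,0.90,0.49,1.67,0.79,0.39,1.61
outdoor,>=2,89,15,FALSE,0.62,0.29,1.30,0.67,0.27,1.62
screen,<0.5,44,3,TRUE,1,NA,NA,1,NA,NA
screen,>=0.5 to <1,173,39,FALSE,3.98,1.17,13.54,3.81,1.04,13.98
screen,>=1,115,30,FALSE,4.82,1.39,16.73,4.36,1.16,16.35
maternal_age,20 to 29,20,4,TRUE,1,NA,NA,1,NA,NA
maternal_age,30 to 39,224,42,FALSE,0.92,0.29,2.90,2.08,0.24,18.31
maternal_age,>=40,88,26,FALSE,1.68,0.51,5.50,4.60,0.45,46.68
maternal_weight_status,Normal,258,58,TRUE,1,NA,NA,1,NA,NA
maternal_weight_status,Underweight,47,9,FALSE,0.82,0.37,1.79,0.77,0.30,1.95
maternal_weight_status,Overweight and obese,27,5,FALSE,0.78,0.28,2.16,0.65,0.21,1.99
maternal_education,<=12,63,15,TRUE,1,NA,NA,1,NA,NA
maternal_education,13 to 14,153,37,FALSE,1.02,0.51,2.03,1.37,0.56,3.37
maternal_education,>=15,116,20,FALSE,0.67,0.31,1.42,0.85,0.32,2.32
maternal_occupation,Professional and manager,162,28,TRUE,1,NA,NA,1,NA,NA
maternal_occupation,"Office work, service, and sales",129,34,FALSE,1.71,0.97,3.01,2.14,1.08,4.25
maternal_occupation,Manual,28,6,FALSE,1.31,0.49,3.51,1.53,0.47,4.97
maternal_occupation,Unemployed,13,4,FALSE,2.13,0.61,7.40,2.50,0.60,10.37
maternal_smoking,No,308,65,TRUE,1,NA,NA,1,NA,NA
maternal_smoking,Yes,24,7,FALSE,1.54,0.61,3.87,1.78,0.58,5.44
paternal_age,20 to 29,12,3,TRUE,1,NA,NA,1,NA,NA
paternal_age,30 to 39,198,38,FALSE,0.71,0.18,2.76,0.42,0.03,5.39
paternal_age,>=40,122,31,FALSE,1.02,0.26,4.02,0.52,0.04,7.70
paternal_weight_status,Normal,235,50,TRUE,1,NA,NA,1,NA,NA
paternal_weight_status,Underweight,12,3,FALSE,1.23,0.32,4.73,0.81,0.18,3.70
paternal_weight_status,Overweight and obese,85,19,FALSE,1.07,0.59,1.94,0.74,0.37,1.49
paternal_education,<=12,113,23,TRUE,1,NA,NA,1,NA,NA
paternal_education,13 to 14,76,20,FALSE,1.40,0.70,2.78,1.30,0.57,2.95
paternal_education,>=15,143,29,FALSE,1.00,0.54,1.84,1.36,0.57,3.23
paternal_occupation,Professional and manager,148,34,TRUE,1,NA,NA,1,NA,NA
paternal_occupation,"Office work, service, and sales",90,17,FALSE,0.78,0.41,1.50,0.58,0.26,1.25
paternal_occupation,Manual,92,21,FALSE,0.99,0.53,1.84,1.01,0.48,2.15
paternal_occupation,Unemployed,2,0,FALSE,NA,NA,NA,NA,NA,NA
paternal_smoking,No,186,43,TRUE,1,NA,NA,1,NA,NA
paternal_smoking,Yes,146,29,FALSE,0.82,0.49,1.40,0.74,0.39,1.42
grandparents,No,272,56,TRUE,1,NA,NA,1,NA,NA
grandparents,Yes,60,16,FALSE,1.40,0.74,2.67,1.95,0.90,4.19
siblings,0,54,14,TRUE,1,NA,NA,1,NA,NA
siblings,1,182,39,FALSE,0.78,0.39,1.58,1.42,0.61,3.28
siblings,>=2,96,19,FALSE,0.71,0.32,1.55,0.78,0.29,2.06
income,Low,91,25,TRUE,1,NA,NA,1,NA,NA
income,Middle,144,28,FALSE,0.64,0.34,1.18,0.48,0.22,1.01
income,High,97,19,FALSE,0.64,0.33,1.27,0.45,0.19,1.07
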