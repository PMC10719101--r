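risk,outcome,rr,ui_ng_lower,ui_ng_upper,ui_wg_lower,ui_wg_upper,bprf,ros,stars,pub_bias,n_studies
Intimate partner violence,Major depressive disorder,2.1,1.86,2.37,1.55,2.83,1.63,0.24,3,No,12
Intimate partner violence,Maternal abortion and miscarriage,2.03,1.68,2.46,1.25,3.31,1.35,0.15,3,No,9
Intimate partner violence,HIV/AIDS,1.58,1.36,1.84,1.06,2.34,1.13,0.06,2,No,6
Intimate partner violence,Anxiety disorders,2.57,1.78,3.72,0.8,8.25,0.97,-0.02,1,No,5
Intimate partner violence,Self-harm,2.99,1.36,6.57,0.29,30.25,0.43,-0.42,1,No,4
Childhood sexual abuse,Alcohol use disorders,1.8,1.62,2.01,1.39,2.33,1.45,0.19,3,No,10
Childhood sexual abuse,Self-harm,1.98,1.73,2.26,1.25,3.12,1.35,0.15,3,No,16
Childhood sexual abuse,Major depressive disorder,1.66,1.51,1.82,1.13,2.44,1.20,0.09,2,No,26
Childhood sexual abuse,Anxiety disorders,1.44,1.3,1.6,1.13,1.85,1.17,0.08,2,No,12
Childhood sexual abuse,Asthma,1.25,1.15,1.35,1.06,1.47,1.09,0.04,2,No,4
Childhood sexual abuse,Type 2 diabetes mellitus,1.11,1.04,1.19,0.96,1.28,0.98,-0.01,1,No,7
Childhood sexual abuse,HIV/AIDS,1.34,1.12,1.61,0.87,2.07,0.93,-0.04,1,No,7
Childhood sexual abuse,Sexually transmitted infections excluding HIV,1.28,1.04,1.57,0.79,2.08,0.85,-0.08,1,No,4
Childhood sexual abuse,Maternal abortion and miscarriage,1.35,1.11,1.66,0.75,2.44,0.83,-0.09,1,No,6
Childhood sexual abuse,Drug use disorders,1.95,1.57,2.43,0.71,5.38,0.83,-0.09,1,No,16
Childhood sexual abuse,Conduct disorder,3.42,1.64,7.14,0.45,25.7,0.63,-0.23,1,No,3
Childhood sexual abuse,Bulimia nervosa,2.95,1.45,5.97,0.37,23.6,0.51,-0.33,1,No,5
Childhood sexual abuse,Schizophrenia,3.7,1.61,8.53,0.26,53.3,0.40,-0.46,1,No,5
Childhood sexual abuse,Ischemic heart disease,1.32,0.86,2.04,0.39,4.47,NA,NA,0,No,3
Childhood sexual abuse,Anorexia nervosa,2.07,0.95,4.51,0.22,19.76,NA,NA,0,No,4
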