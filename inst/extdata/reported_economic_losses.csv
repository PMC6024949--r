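endpoint,ahc_2014,vsl_2014,ahc_2015,vsl_2015,ahc_2016,vsl_2016
all_cause_mortality,256.32,1157.59,230.89,1061.69,214.16,1018.62
cardiovascular_mortality,65.46,295.48,59.03,271.44,54.84,260.75
respiratory_mortality,39.19,177,35.23,162.02,32.63,155.24
lung_cancer_mortality,84.84,383.9,75.7,348.39,69.68,331.86
cardiovascular_hospitalization,12.2,12.2,10.95,10.95,10.28,10.28
chronic_bronchitis,42.48,42.48,39,39,37.44,37.44
acute_bronchitis,0.35,0.35,0.31,0.31,0.29,0.29
asthma_attack,6.57,6.57,5.8,5.8,5.4,5.4
total_economic_loss,317.93,1219.19,286.97,1117.76,267.38,1072.02
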