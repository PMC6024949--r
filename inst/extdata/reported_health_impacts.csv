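endpoint,y2014,y2015,y2016
all_cause_mortality,278444,238622,216164
cardiovascular_mortality,71058,60991,55321
respiratory_mortality,42590,36431,32959
lung_cancer_mortality,92512,78444,70557
cardiovascular_hospitalization,1001233,851497,767387
chronic_bronchitis,185798,159366,144459
acute_bronchitis,1034080,881692,795978
asthma_attack,19197994,15935983,14130036
affected_population,21697549,18067160,16054024
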