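name,category,duration,beta,baseline_incidence,cost_rule,unit_cost,vsl_weight,in_affected_total
all_cause_mortality,mortality,chronic,0.00096,0.007,mortality_bound,0,0,TRUE
cardiovascular_mortality,mortality,chronic,0.00053,0.0046,mortality_bound,0,0,FALSE
respiratory_mortality,mortality,chronic,0.00143,0.0009,mortality_bound,0,0,FALSE
lung_cancer_mortality,mortality,chronic,0.00124,0.0006,mortality_bound,0,0,FALSE
cardiovascular_hospitalization,morbidity,acute,0.00068,0.0127,per_case_fixed,1379,0,TRUE
chronic_bronchitis,morbidity,chronic,0.00448,0.0039,vsl_fraction,0,0.055,TRUE
acute_bronchitis,morbidity,acute,0.00448,0.0223,per_case_fixed,38.4,0,TRUE
asthma_attack,morbidity,acute,0.0021,0.1,per_case_fixed,34.2,0,TRUE
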