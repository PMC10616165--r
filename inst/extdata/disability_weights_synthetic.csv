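kind,level,weight
mrs,0,0
mrs,1,0.019
mrs,2,0.07
mrs,3,0.316
mrs,4,0.552
mrs,5,0.588
comorbidity,hypertension,0.02
comorbidity,cardiopathy,0.072
comorbidity,copd,0.188
comorbidity,renal,0.104
comorbidity,diabetes,0.049
comorbidity,extracranial_neoplasia,0.288
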