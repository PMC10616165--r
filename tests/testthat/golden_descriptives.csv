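# generated by neuroburden 0.1.0
# seed: 7
section,label,value,n_missing
baseline,n,5,0
baseline,age_years_mean_sd,64.0 ± 18.5,0
baseline,male_sex,3 (60.0),0
insurance,public,5 (100.0),0
insurance,private,0 (0.0),0
admission_type,elective,0 (0.0),0
admission_type,emergency,5 (100.0),0
location_before_icu,emergency_department,5 (100.0),0
location_before_icu,operating_room,0 (0.0),0
location_before_icu,ward,0 (0.0),0
location_before_icu,other,0 (0.0),0
severity,gcs_median_iqr,14.0 (14.0-14.0),0
severity,apache2_median_iqr,10.0 (10.0-10.0),0
severity,saps3_median_iqr,40.0 (40.0-40.0),0
severity,sofa_median_iqr,2.0 (2.0-2.0),0
comorbidities,hypertension,1 (20.0),0
comorbidities,cardiopathy,1 (20.0),0
comorbidities,copd,1 (20.0),0
comorbidities,renal,0 (0.0),0
comorbidities,diabetes,0 (0.0),0
comorbidities,extracranial_neoplasia,0 (0.0),0
diagnosis,NPO,0 (0.0),0
diagnosis,TBI,0 (0.0),0
diagnosis,IS,5 (100.0),0
diagnosis,ENC,0 (0.0),0
diagnosis,seizures,0 (0.0),0
diagnosis,ICH,0 (0.0),0
diagnosis,SAH,0 (0.0),0
diagnosis,SNI,0 (0.0),0
diagnosis,SCI,0 (0.0),0
diagnosis,NMD,0 (0.0),0
hs,hypotension,0 (0.0),0
hs,hypoxemia,0 (0.0),0
hs,hyperthermia,0 (0.0),0
hs,hypercapnia,0 (0.0),0
hs,hypocapnia,0 (0.0),0
hs,hypoglycaemia,0 (0.0),0
hs,hyponatremia,0 (0.0),0
hs,hypothermia,0 (0.0),0
hs,intracranial_hypertension,0 (0.0),0
hs,herniation,0 (0.0),0
hs_count,zero,5 (100.0),0
hs_count,one,0 (0.0),0
hs_count,two,0 (0.0),0
hs_count,three_plus,0 (0.0),0
outcome,icu_discharge,3 (60.0),0
outcome,transfer,0 (0.0),0
outcome,continued_hospitalization,0 (0.0),0
outcome,death,2 (40.0),0
mrs,mrs_0,1 (20.0),0
mrs,mrs_1,0 (0.0),0
mrs,mrs_2,0 (0.0),0
mrs,mrs_3,1 (20.0),0
mrs,mrs_4,0 (0.0),0
mrs,mrs_5,1 (20.0),0
mrs,mrs_6,2 (40.0),0
outcome,unfavourable_mrs_4_6,3 (60.0),0
outcome,los_days_median_iqr,5.0 (5.0-5.0),0
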