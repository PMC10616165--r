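factor,level,outcome,exposed_events,exposed_nonevents,ref_events,ref_nonevents,or_printed,ci_low_printed,ci_high_printed
hs_category,one,mortality,35,283,22,478,2.687,1.545,4.672
hs_category,two,mortality,49,154,22,478,6.91,4.049,11.801
hs_category,three_plus,mortality,82,91,22,478,19.578,11.625,32.972
hs_category,one,unfavourable,111,207,114,380,1.787,1.309,2.44
hs_category,two,unfavourable,120,82,114,380,4.878,3.437,6.924
hs_category,three_plus,unfavourable,137,36,114,380,12.685,8.313,19.356
insurance,public,mortality,137,454,51,552,3.266,2.313,4.610
insurance,public,unfavourable,318,273,164,432,3.068,2.409,3.908
admission_type,emergency,mortality,181,696,7,310,11.517,5.350,24.793
admission_type,emergency,unfavourable,441,430,41,275,6.879,4.828,9.801
sex,male,unfavourable,270,345,212,360,1.329,1.053,1.677
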