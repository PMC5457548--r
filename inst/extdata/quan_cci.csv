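category,icd9_prefix,weight
myocardial_infarction,410,1
myocardial_infarction,412,1
congestive_heart_failure,39891,1
congestive_heart_failure,40201,1
congestive_heart_failure,40211,1
congestive_heart_failure,40291,1
congestive_heart_failure,40401,1
congestive_heart_failure,40403,1
congestive_heart_failure,40411,1
congestive_heart_failure,40413,1
congestive_heart_failure,40491,1
congestive_heart_failure,40493,1
congestive_heart_failure,4254,1
congestive_heart_failure,4255,1
congestive_heart_failure,4256,1
congestive_heart_failure,4257,1
congestive_heart_failure,4258,1
congestive_heart_failure,4259,1
congestive_heart_failure,428,1
peripheral_vascular,0930,1
peripheral_vascular,4373,1
peripheral_vascular,440,1
peripheral_vascular,441,1
peripheral_vascular,4431,1
peripheral_vascular,4432,1
peripheral_vascular,4433,1
peripheral_vascular,4434,1
peripheral_vascular,4435,1
peripheral_vascular,4436,1
peripheral_vascular,4437,1
peripheral_vascular,4438,1
peripheral_vascular,4439,1
peripheral_vascular,4471,1
peripheral_vascular,5571,1
peripheral_vascular,5579,1
peripheral_vascular,V434,1
cerebrovascular,36234,1
cerebrovascular,430,1
cerebrovascular,431,1
cerebrovascular,432,1
cerebrovascular,433,1
cerebrovascular,434,1
cerebrovascular,435,1
cerebrovascular,436,1
cerebrovascular,437,1
cerebrovascular,438,1
dementia,290,1
dementia,2941,1
dementia,3312,1
chronic_pulmonary,4168,1
chronic_pulmonary,4169,1
chronic_pulmonary,490,1
chronic_pulmonary,491,1
chronic_pulmonary,492,1
chronic_pulmonary,493,1
chronic_pulmonary,494,1
chronic_pulmonary,495,1
chronic_pulmonary,496,1
chronic_pulmonary,497,1
chronic_pulmonary,498,1
chronic_pulmonary,499,1
chronic_pulmonary,500,1
chronic_pulmonary,501,1
chronic_pulmonary,502,1
chronic_pulmonary,503,1
chronic_pulmonary,504,1
chronic_pulmonary,505,1
chronic_pulmonary,5064,1
chronic_pulmonary,5081,1
chronic_pulmonary,5088,1
rheumatologic,4465,1
rheumatologic,7100,1
rheumatologic,7101,1
rheumatologic,7102,1
rheumatologic,7103,1
rheumatologic,7104,1
rheumatologic,7140,1
rheumatologic,7141,1
rheumatologic,7142,1
rheumatologic,7148,1
rheumatologic,725,1
peptic_ulcer,531,1
peptic_ulcer,532,1
peptic_ulcer,533,1
peptic_ulcer,534,1
liver_mild,07022,1
liver_mild,07023,1
liver_mild,07032,1
liver_mild,07033,1
liver_mild,07044,1
liver_mild,07054,1
liver_mild,0706,1
liver_mild,0709,1
liver_mild,570,1
liver_mild,571,1
liver_mild,5733,1
liver_mild,5734,1
liver_mild,5738,1
liver_mild,5739,1
liver_mild,V427,1
diabetes,2500,1
diabetes,2501,1
diabetes,2502,1
diabetes,2503,1
diabetes,2508,1
diabetes,2509,1
diabetes_complicated,2504,2
diabetes_complicated,2505,2
diabetes_complicated,2506,2
diabetes_complicated,2507,2
hemiplegia_paraplegia,3341,2
hemiplegia_paraplegia,342,2
hemiplegia_paraplegia,343,2
hemiplegia_paraplegia,3440,2
hemiplegia_paraplegia,3441,2
hemiplegia_paraplegia,3442,2
hemiplegia_paraplegia,3443,2
hemiplegia_paraplegia,3444,2
hemiplegia_paraplegia,3445,2
hemiplegia_paraplegia,3446,2
hemiplegia_paraplegia,3449,2
renal,40301,2
renal,40311,2
renal,40391,2
renal,40402,2
renal,40403,2
renal,40412,2
renal,40413,2
renal,40492,2
renal,40493,2
renal,582,2
renal,5830,2
renal,5831,2
renal,5832,2
renal,5833,2
renal,5834,2
renal,5835,2
renal,5836,2
renal,5837,2
renal,585,2
renal,586,2
renal,5880,2
renal,V420,2
renal,V451,2
renal,V56,2
malignancy,140,2
malignancy,141,2
malignancy,142,2
malignancy,143,2
malignancy,144,2
malignancy,145,2
malignancy,146,2
malignancy,147,2
malignancy,148,2
malignancy,149,2
malignancy,150,2
malignancy,151,2
malignancy,152,2
malignancy,153,2
malignancy,154,2
malignancy,155,2
malignancy,156,2
malignancy,157,2
malignancy,158,2
malignancy,159,2
malignancy,160,2
malignancy,161,2
malignancy,162,2
malignancy,163,2
malignancy,164,2
malignancy,165,2
malignancy,166,2
malignancy,167,2
malignancy,168,2
malignancy,169,2
malignancy,170,2
malignancy,171,2
malignancy,172,2
malignancy,174,2
malignancy,175,2
malignancy,176,2
malignancy,177,2
malignancy,178,2
malignancy,179,2
malignancy,180,2
malignancy,181,2
malignancy,182,2
malignancy,183,2
malignancy,184,2
malignancy,185,2
malignancy,186,2
malignancy,187,2
malignancy,188,2
malignancy,189,2
malignancy,190,2
malignancy,191,2
malignancy,192,2
malignancy,193,2
malignancy,194,2
malignancy,195,2
malignancy,200,2
malignancy,201,2
malignancy,202,2
malignancy,203,2
malignancy,204,2
malignancy,205,2
malignancy,206,2
malignancy,207,2
malignancy,208,2
malignancy,2386,2
liver_severe,4560,3
liver_severe,4561,3
liver_severe,4562,3
liver_severe,5722,3
liver_severe,5723,3
liver_severe,5724,3
liver_severe,5725,3
liver_severe,5726,3
liver_severe,5727,3
liver_severe,5728,3
metastatic_solid_tumor,196,6
metastatic_solid_tumor,197,6
metastatic_solid_tumor,198,6
metastatic_solid_tumor,199,6
aids_hiv,042,6
aids_hiv,043,6
aids_hiv,044,6
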