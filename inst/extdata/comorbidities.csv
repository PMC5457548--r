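name,icd9_prefix
cardiovascular,410
cardiovascular,4110
cardiovascular,41181
cardiovascular,41189
cardiovascular,4111
cardiovascular,413
cardiovascular,4275
cardiovascular,4271
cardiovascular,4274
cardiovascular,4273
cardiovascular,39891
cardiovascular,428
cardiovascular,4140
cardiovascular,4141
cardiovascular,4148
cardiovascular,4149
cardiovascular,4293
cardiovascular,4029
cardiovascular,430
cardiovascular,431
cardiovascular,432
cardiovascular,433
cardiovascular,434
cardiovascular,435
cardiovascular,436
cardiovascular,437
cardiovascular,42789
hepatitis_c,07041
hepatitis_c,07044
hepatitis_c,07051
hepatitis_c,07054
hepatitis_c,0707
hepatitis_c,V0262
diabetes,250
obesity,2780
drug_abuse,304
drug_abuse,3052
drug_abuse,3053
drug_abuse,3054
drug_abuse,3055
drug_abuse,3056
drug_abuse,3057
drug_abuse,3058
drug_abuse,3059
hiv_aids,042
hiv_aids,V08
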