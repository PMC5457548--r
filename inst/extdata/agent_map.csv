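agent_code,agent_class,branded
PP1M,pp1m,TRUE
ARIP,aripiprazole,FALSE
ASEN,asenapine,TRUE
ILOP,iloperidone,TRUE
LURA,lurasidone,TRUE
OLAN,olanzapine,FALSE
PALI,paliperidone,TRUE
QUET,quetiapine,FALSE
RISP,risperidone,FALSE
ZIPR,ziprasidone,FALSE
HALO,typical_oral_ap,FALSE
CHLO,typical_oral_ap,FALSE
HALD,typical_lai,FALSE
FLUD,typical_lai,FALSE
RLAI,other_atypical_lai,TRUE
LORA,anxiolytic,FALSE
CLON,anxiolytic,FALSE
ALPR,anxiolytic,FALSE
SERT,antidepressant,FALSE
FLUO,antidepressant,FALSE
CITA,antidepressant,FALSE
VALP,mood_stabilizer,FALSE
LITH,mood_stabilizer,FALSE
LAMO,mood_stabilizer,TRUE
OTHR,other,FALSE
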