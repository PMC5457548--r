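"patient_id","start_date","end_date","capitated","dual_coverage"
"EX01","2009-01-01","2011-12-31",TRUE,FALSE
"EX02","2009-01-01","2011-12-31",FALSE,FALSE
"EX03","2009-01-01","2011-12-31",TRUE,TRUE
"EX04","2009-01-01","2011-12-31",FALSE,FALSE
"EX05","2009-01-01","2011-12-31",TRUE,FALSE
"EX06","2009-01-01","2011-12-31",FALSE,TRUE
"EX07","2010-01-01","2011-12-31",TRUE,FALSE
"EX08","2009-01-01","2010-09-15",FALSE,FALSE
"EX09","2009-01-01","2011-12-31",TRUE,TRUE
"EX10","2009-01-01","2011-12-31",FALSE,FALSE
"EX11","2009-01-01","2011-12-31",TRUE,FALSE
"EX12","2009-01-01","2011-12-31",FALSE,TRUE
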