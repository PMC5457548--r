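"patient_id","dispense_date","agent_code","agent_class","days_supply","paid_amount","branded","service_year"
"EX01","2010-06-01","PP1M","pp1m",30,1100,TRUE,2010
"EX01","2010-07-01","PP1M","pp1m",30,1100,TRUE,2010
"EX01","2010-08-01","PP1M","pp1m",30,1100,TRUE,2010
"EX01","2010-09-01","PP1M","pp1m",30,1100,TRUE,2010
"EX01","2010-10-01","PP1M","pp1m",30,1100,TRUE,2010
"EX01","2010-11-01","PP1M","pp1m",30,1100,TRUE,2010
"EX01","2010-12-01","PP1M","pp1m",30,1100,TRUE,2010
"EX01","2009-12-01","QUET","quetiapine",30,150,FALSE,2009
"EX01","2010-01-10","LORA","anxiolytic",30,20,FALSE,2010
"EX01","2010-02-15","CLON","anxiolytic",30,20,FALSE,2010
"EX02","2010-06-01","RISP","risperidone",30,150,FALSE,2010
"EX02","2010-06-25","RISP","risperidone",30,150,FALSE,2010
"EX02","2010-07-20","RISP","risperidone",30,150,FALSE,2010
"EX02","2010-08-15","RISP","risperidone",30,150,FALSE,2010
"EX03","2010-06-01","QUET","quetiapine",30,150,FALSE,2010
"EX03","2010-09-30","QUET","quetiapine",30,150,FALSE,2010
"EX04","2010-02-21","OLAN","olanzapine",30,150,FALSE,2010
"EX04","2010-06-01","OLAN","olanzapine",30,150,FALSE,2010
"EX04","2010-06-20","OLAN","olanzapine",30,150,FALSE,2010
"EX05","2010-06-01","ARIP","aripiprazole",30,150,FALSE,2010
"EX05","2010-06-29","ARIP","aripiprazole",30,150,FALSE,2010
"EX06","2010-06-01","RISP","risperidone",30,150,FALSE,2010
"EX06","2010-06-22","RISP","risperidone",30,150,FALSE,2010
"EX07","2010-06-01","QUET","quetiapine",30,150,FALSE,2010
"EX07","2010-06-26","QUET","quetiapine",30,150,FALSE,2010
"EX08","2010-06-01","OLAN","olanzapine",30,150,FALSE,2010
"EX08","2010-06-25","OLAN","olanzapine",30,150,FALSE,2010
"EX10","2010-06-01","QUET","quetiapine",30,150,FALSE,2010
"EX10","2010-06-20","OLAN","olanzapine",30,150,FALSE,2010
"EX11","2010-06-01","LURA","lurasidone",30,150,TRUE,2010
"EX11","2010-07-15","LURA","lurasidone",30,150,TRUE,2010
"EX11","2010-08-20","LURA","lurasidone",30,150,TRUE,2010
"EX12","2010-06-01","PP1M","pp1m",30,1100,TRUE,2010
"EX12","2010-06-28","PP1M","pp1m",30,1100,TRUE,2010
"EX12","2010-06-01","RISP","risperidone",30,150,FALSE,2010
"EX12","2010-06-21","RISP","risperidone",30,150,FALSE,2010
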