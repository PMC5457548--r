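"patient_id","birth_date","sex","race","region","state"
"EX01","1980-03-05","male","white","urban","MO"
"EX02","1970-01-10","female","black","rural","NJ"
"EX03","1982-01-01","male","white","urban","IA"
"EX04","1983-01-01","female","black","suburban","KS"
"EX05","1985-06-15","male","white","urban","MO"
"EX06","1992-08-01","female","black","rural","MS"
"EX07","1980-01-01","male","white","urban","MO"
"EX08","1975-05-05","female","other","suburban","NJ"
"EX09","1985-02-10","male","white","urban","IA"
"EX10","1984-01-01","female","black","rural","KS"
"EX11","1988-04-20","male","white","suburban","MO"
"EX12","1975-03-03","female","black","urban","NJ"
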