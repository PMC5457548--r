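"patient_id","start_date","end_date","service_category","dx_codes","paid_amount","agent_code","branded","service_year"
"EX01","2010-01-15","2010-01-15","outpatient","295.30",120,"",FALSE,2010
"EX01","2010-03-10","2010-03-10","outpatient","295.30",120,"",FALSE,2010
"EX02","2010-02-01","2010-02-01","outpatient","295.90;401.9",120,"",FALSE,2010
"EX02","2010-04-05","2010-04-05","outpatient","295.90;401.9",120,"",FALSE,2010
"EX03","2010-01-20","2010-01-20","outpatient","295.30",120,"",FALSE,2010
"EX03","2010-02-20","2010-02-20","outpatient","295.30",120,"",FALSE,2010
"EX04","2010-01-05","2010-01-05","outpatient","295.62",120,"",FALSE,2010
"EX04","2010-05-05","2010-05-05","outpatient","295.62",120,"",FALSE,2010
"EX05","2010-03-15","2010-03-15","outpatient","295.30",120,"",FALSE,2010
"EX05","2010-04-10","2010-04-10","outpatient","296.30",120,"",FALSE,2010
"EX06","2010-01-11","2010-01-11","outpatient","295.30",120,"",FALSE,2010
"EX06","2010-02-11","2010-02-11","outpatient","295.30",120,"",FALSE,2010
"EX07","2010-02-01","2010-02-01","outpatient","295.70",120,"",FALSE,2010
"EX07","2010-03-01","2010-03-01","outpatient","295.70",120,"",FALSE,2010
"EX08","2010-01-09","2010-01-09","outpatient","295.30",120,"",FALSE,2010
"EX08","2010-02-09","2010-02-09","outpatient","295.30",120,"",FALSE,2010
"EX09","2010-06-01","2010-06-01","other","295.30",1150,"PP1M",TRUE,2010
"EX09","2010-06-29","2010-06-29","other","295.30",1150,"PP1M",TRUE,2010
"EX09","2010-01-12","2010-01-12","outpatient","295.32",120,"",FALSE,2010
"EX09","2010-02-14","2010-02-14","outpatient","295.32",120,"",FALSE,2010
"EX10","2010-01-03","2010-01-03","outpatient","295.30",120,"",FALSE,2010
"EX10","2010-02-03","2010-02-03","outpatient","295.30",120,"",FALSE,2010
"EX11","2010-01-25","2010-01-25","outpatient","295.90",120,"",FALSE,2010
"EX11","2010-03-25","2010-03-25","outpatient","295.90",120,"",FALSE,2010
"EX12","2010-01-18","2010-01-18","outpatient","295.30",120,"",FALSE,2010
"EX12","2010-02-18","2010-02-18","outpatient","295.30",120,"",FALSE,2010
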