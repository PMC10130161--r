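"subject_id","histology","smoker","tumor_size_cm","stage","kras","egfr","os_months","os_event","rfs_months","rfs_event"
"P01","ADC",1,2.5,"I","wt","wt",34.2,1,20.1,1
"P02","ADC",0,4.1,"II","mut","wt",12.8,1,8.4,1
"P03","SCC",1,3,"III","wt","mut",48,0,48,0
"P04","ADC",1,1.8,"I","wt","wt",22.5,1,15.2,1
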