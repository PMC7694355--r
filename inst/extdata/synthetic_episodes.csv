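"participant_id","episode_id","admission_date","admission_time","separation_date","separation_time","admission_type","admission_source","separation_mode","campus","care_type"
"P0001","E00001","2008-04-04","12:44","2008-04-15","01:44","emergency_this_hospital","ed_or_direct","left_against_advice","C1","acute"
"P0001","E00002","2009-03-15","10:21","2009-03-17","03:11","emergency_this_hospital","ed_or_direct","died_in_hospital","C1","geriatric"
"P0002","E00003","2008-04-16","03:13","2008-04-18","12:40","emergency_this_hospital","ed_or_direct","died_in_hospital","C1","rehabilitation"
"P0002","E00004","2008-05-01","12:52","2008-05-05","00:22","other_emergency","ed_or_direct","left_against_advice","C1","acute"
"P0003","E00005","2008-03-16","06:33","2008-03-17","07:20","emergency_this_hospital","ed_or_direct","left_against_advice","C1","acute"
"P0003","E00006","2009-01-26","20:18","2009-02-15","07:53","statistical_admission","ed_or_direct","discharge_home","C3","geriatric"
"P0003","E00007","2009-12-01","11:37","2009-12-02","16:53","emergency_this_hospital","ed_or_direct","died_in_hospital","C3","rehabilitation"
"P0003","E00008","2010-01-26","23:15","2010-01-29","16:23","emergency_this_hospital","ed_or_direct","left_against_advice","C3","rehabilitation"
"P0003","E00009","2010-03-27","01:30","2010-03-31","11:05","waiting_list","ed_or_direct","discharge_home","C2","geriatric"
"P0003","E00010","2010-09-07","16:19","2010-09-17","02:03","statistical_admission","ed_or_direct","left_against_advice","C1","geriatric"
"P0003","E00011","2011-05-19","04:59","2011-05-29","19:54","waiting_list","ed_or_direct","left_against_advice","C2","acute"
"P0004","E00012","2008-03-20","01:23","2008-03-22","00:08","emergency_this_hospital","ed_or_direct","died_in_hospital","C3","geriatric"
"P0004","E00013","2008-09-28","15:21","2008-10-04","12:02","other_admission","ed_or_direct","died_in_hospital","C1","geriatric"
"P0004","E00014","2009-02-06","07:15","2009-02-21","23:18","other_emergency","ed_or_direct","died_in_hospital","C2","geriatric"
"P0004","E00015","2009-10-18","08:11","2009-10-23","14:58","emergency_this_hospital","ed_or_direct","discharge_home","C3","rehabilitation"
"P0004","E00016","2011-09-18","12:11","2011-09-20","05:34","emergency_this_hospital","ed_or_direct","transfer_other_hospital","C2","rehabilitation"
"P0004","E00017","2011-09-20","13:46","2011-09-22","04:06","statistical_admission","transfer","transfer_other_hospital","C1","rehabilitation"
"P0004","E00018","2011-09-22","13:02","2011-10-08","19:54","statistical_admission","transfer","discharge_home","C3","acute"
"P0004","E00019","2011-11-21","18:40","2011-11-22","15:44","maternity","ed_or_direct","discharge_home","C2","geriatric"
"P0005","E00020","2008-09-19","22:09","2008-09-20","12:23","maternity","ed_or_direct","died_in_hospital","C1","acute"
"P0005","E00021","2013-11-26","12:50","2013-12-07","08:20","waiting_list","ed_or_direct","died_in_hospital","C2","rehabilitation"
"P0008","E00022","2008-07-01","23:08","2008-07-17","17:26","waiting_list","ed_or_direct","died_in_hospital","C1","geriatric"
"P0008","E00023","2008-09-27","01:01","2008-10-01","06:53","emergency_this_hospital","ed_or_direct","transfer_other_hospital","C2","rehabilitation"
"P0008","E00024","2008-10-01","16:48","2008-10-04","17:32","statistical_admission","transfer","died_in_hospital","C3","acute"
"P0008","E00025","2008-10-13","10:26","2008-10-14","15:08","waiting_list","ed_or_direct","died_in_hospital","C3","rehabilitation"
"P0008","E00026","2009-03-21","22:49","2009-03-23","14:23","emergency_this_hospital","ed_or_direct","discharge_home","C2","geriatric"
"P0008","E00027","2010-07-07","06:56","2010-07-12","18:47","statistical_admission","ed_or_direct","discharge_home","C2","rehabilitation"
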