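"participant_id","visit_id","arrival_date","arrival_time","departure_date","departure_time","departure_status","campus","visit_type","referred_by"
"P0001","V00001","2008-04-04","11:03","2008-04-04","20:29","procedure_room_this_campus","C3","emergency","ambulance"
"P0001","V00002","2008-07-31","00:59","2008-07-31","06:41","usual_residence","C1","return_visit","self"
"P0001","V00003","2009-03-15","10:21","2009-03-15","19:03","ward_this_hospital","C2","emergency","self"
"P0001","V00004","2010-09-16","03:32","2010-09-16","04:50","left_before_treatment_complete","C1","emergency","gp"
"P0002","V00005","2008-04-16","00:38","2008-04-16","05:23","transfer_other_campus","C1","emergency","self"
"P0003","V00006","2008-03-16","06:33","2008-03-16","12:37","ward_this_hospital","C1","return_visit","gp"
"P0003","V00007","2008-07-17","09:20","2008-07-17","10:54","died_in_ed","C2","return_visit","ambulance"
"P0003","V00008","2009-12-01","11:19","2009-12-01","12:33","procedure_room_this_campus","C3","emergency","gp"
"P0003","V00009","2009-12-11","06:33","2009-12-11","15:58","left_before_treatment_complete","C2","return_visit","self"
"P0003","V00010","2009-12-11","17:15","2009-12-11","19:42","left_before_treatment_complete","C1","return_visit","self"
"P0003","V00011","2010-01-26","20:22","2010-01-26","23:48","ward_this_hospital","C3","emergency","gp"
"P0003","V00012","2010-06-11","20:43","2010-06-11","22:27","left_before_treatment_complete","C2","emergency","gp"
"P0003","V00013","2010-06-12","01:00","2010-06-12","04:01","left_before_treatment_complete","C1","return_visit","gp"
"P0003","V00014","2010-10-18","04:31","2010-10-18","11:29","left_before_treatment_complete","C3","emergency","self"
"P0003","V00015","2010-12-25","02:02","2010-12-25","06:10","usual_residence","C2","return_visit","self"
"P0003","V00016","2011-05-19","02:07","2011-05-19","05:20","ward_this_hospital","C2","return_visit","gp"
"P0004","V00017","2008-03-19","17:52","2008-03-20","01:54","died_in_ed","C2","return_visit","self"
"P0004","V00018","2009-08-16","11:18","2009-08-16","16:02","died_in_ed","C1","emergency","ambulance"
"P0004","V00019","2009-09-28","19:13","2009-09-28","22:21","usual_residence","C1","emergency","ambulance"
"P0004","V00020","2009-10-18","08:11","2009-10-18","10:42","procedure_room_this_campus","C2","emergency","self"
"P0004","V00021","2010-02-27","19:04","2010-02-27","21:12","died_in_ed","C2","return_visit","gp"
"P0004","V00022","2010-02-28","01:20","2010-02-28","06:15","usual_residence","C2","emergency","gp"
"P0004","V00023","2010-05-23","01:59","2010-05-23","04:59","left_before_treatment_complete","C2","return_visit","self"
"P0004","V00024","2010-10-29","13:56","2010-10-29","20:19","died_in_ed","C1","return_visit","gp"
"P0004","V00025","2011-09-18","09:43","2011-09-18","12:32","transfer_other_campus","C2","return_visit","gp"
"P0004","V00026","2011-11-21","18:40","2011-11-21","23:20","left_before_treatment_complete","C1","return_visit","gp"
"P0006","V00027","2009-05-31","21:55","2009-06-01","03:57","usual_residence","C1","emergency","ambulance"
"P0008","V00028","2008-09-27","01:01","2008-09-27","07:25","usual_residence","C1","return_visit","gp"
"P0008","V00029","2008-10-07","20:30","2008-10-07","21:30","usual_residence","C2","emergency","ambulance"
"P0008","V00030","2009-03-21","22:53","2009-03-22","03:09","ward_this_hospital","C2","return_visit","gp"
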