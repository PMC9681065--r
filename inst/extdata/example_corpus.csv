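record_id,study_id,year_online,year_print,scale_type,control_mean,treatment_mean,control_sd,treatment_sd,control_n,treatment_n,co2_uatm,species,life_stage,cue_type,behaviour_metric,is_sham,is_fluctuating_co2,is_procedural_control,direction_opposite
r001,s2009_01,2009,2009,percentage,90,0,6.5,0,12,12,1000,species_01,larva,predator_cue,pct_time_in_cue_arm,FALSE,FALSE,FALSE,FALSE
r002,s2009_01,2009,2009,percentage,82,14,9.1,7.8,12,11,1000,species_01,larva,habitat_cue,pct_time_in_cue_arm,FALSE,FALSE,FALSE,FALSE
r003,s2010_01,2010,2011,percentage,0,100,0,0,10,10,850,species_02,larva,predator_cue,pct_time_in_cue_arm,FALSE,FALSE,FALSE,FALSE
r004,s2013_01,2013,2013,proportion,0.62,0.35,0.18,0.2,15,15,750,species_03,juvenile,alarm_cue,pct_time_in_cue_arm,FALSE,FALSE,FALSE,FALSE
r005,s2013_01,2013,2013,proportion,0.55,0.52,0.2,0.22,15,15,750,species_03,juvenile,none,activity_level,TRUE,FALSE,FALSE,FALSE
r006,s2016_01,2016,2016,continuous,24.5,14.2,5.3,4.9,20,18,1300,species_04,adult,predator_cue,feeding_strikes,FALSE,TRUE,FALSE,FALSE
r007,s2018_01,2018,2018,percentage,61,44,12,11,25,25,600,species_05,juvenile,alarm_cue,pct_time_in_cue_arm,FALSE,FALSE,FALSE,TRUE
r008,s2018_01,2018,2018,percentage,abc,40,10,10,25,25,600,species_05,juvenile,habitat_cue,pct_time_in_cue_arm,FALSE,FALSE,FALSE,FALSE
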