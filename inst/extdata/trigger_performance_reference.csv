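trigger_id,triggers_per_100,adrs_per_100,ppv_pct
ptt_gt_50,2.2,2.2,100.0
skin_rash,1.5,1.5,100.0
protamine,0.7,0.7,100.0
hydroxyzine,0.7,0.7,100.0
inr_gt_3,6.7,3.7,55.6
abrupt_medication_stop,49.6,22.2,44.8
glucose_lt_50,64.4,17.0,26.4
platelets_lt_50000,15.6,3.7,23.8
hb_ht_drop_25pct,48.9,5.2,10.6
ondansetron,25.9,2.2,8.6
bun_cr_rise_2x,58.5,2.2,3.8
potassium_lt_3_0,51.1,1.5,2.9
oversedation_hypotension,112.6,3.0,2.6
hydrocortisone,72.6,1.5,2.0
bromopride,43.7,0.7,1.7
metoclopramide,71.9,0.7,1.0
potassium_gt_5_5,96.3,0.7,0.8
sodium_lt_135,105.9,0.7,0.7
methylprednisolone,23.0,0.0,0.0
phytomenadione,8.9,0.0,0.0
prednisone,7.4,0.0,0.0
diphenhydramine,5.2,0.0,0.0
promethazine,2.2,0.0,0.0
naloxone,0.0,0.0,0.0
flumazenil,0.0,0.0,0.0
dexchlorpheniramine,0.0,0.0,0.0
loratadine,0.0,0.0,0.0
patient_fall,0.0,0.0,0.0
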