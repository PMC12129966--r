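quantity,value
n_records,135
n_g_icu,76
n_c19_icu,59
n_male,74
total_trigger_hits,1182
patients_with_adr,55
patients_with_adr_g_icu,24
patients_with_adr_c19_icu,31
total_adrs,85
adrs_trigger_detected,65
adrs_non_trigger,20
deaths,94
matching_spontaneous_reports,0
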