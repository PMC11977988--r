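participant_id,date,nonwear_minutes,wear_minutes,valid_day
T01,2021-09-12,0,1440,TRUE
T01,2021-09-13,840,600,TRUE
T01,2021-09-14,40,1400,TRUE
T01,2021-09-15,0,1440,TRUE
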