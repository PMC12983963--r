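calf_id,date,temperature_c,humidity_pct,wind,weight_kg,height_cm,diagonal_cm,chest_cm,lying_min,standing_min,rr_per_min,urination_n
calf_01,2022-11-09,1.21,71.3,9.34,36.7,76,55,80,1290.39,149.61,34,2
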