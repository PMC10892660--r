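species,body_weight_ref_kg,cardiac_output_ml_min,blood_volume_ml,arterial_frac,hematocrit,mppgl_mg_per_g
rat,0.25,80,16.85,0.333,0.45,44.8
human,70,5600,5600,0.334,0.45,40
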