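species,segment,lumen_volume_ml,transit_rate_per_h,surface_area_cm2
rat,stomach,3,2.77,0
rat,si1,1.5,2.0,240
rat,si2,1.5,2.0,240
rat,si3,1.5,2.0,240
human,stomach,50,2.77,0
human,si1,35,0.9,7300
human,si2,35,0.9,7300
human,si3,35,0.9,7300
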