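compound,species,study,mrd,ratio_cmax,ratio_aucinf
saxagliptin,rat,iv 10 mg/kg,1.92,2.05,1.04
saxagliptin,rat,po 5 mg/kg,1.14,1.46,1.13
saxagliptin,human,po 2.5 mg,1.32,1.22,0.96
saxagliptin,human,po 5 mg (a),1.17,1.32,1.08
saxagliptin,human,po 5 mg (b),1.60,1.15,0.73
nicardipine,rat,po 12 mg/kg,1.69,0.91,1.33
nicardipine,rat,po 15 mg/kg,2.08,0.68,0.85
nicardipine,human,po 20 mg,1.92,0.72,1.50
nicardipine,human,po 40 mg,1.66,0.63,0.86
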