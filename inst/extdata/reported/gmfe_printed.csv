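compound,species,gmfe_cmax,gmfe_aucinf
saxagliptin,rat,1.73,1.08
saxagliptin,human,1.23,1.16
nicardipine,rat,1.27,1.15
nicardipine,human,1.48,1.33
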