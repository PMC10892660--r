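species,study,parameter,unit,observed,predicted,ratio_printed
rat,po 5 mg/kg,Cmax,ng/mL,98.5,144,1.46
rat,po 5 mg/kg,t_half,h,1.82,1.63,0.90
rat,po 5 mg/kg,AUCinf,ng.h/mL,157,177,1.13
human,po 2.5 mg,Cmax,ng/mL,7.89,9.64,1.22
human,po 2.5 mg,t_half,h,7.21,5.33,0.74
human,po 2.5 mg,AUCinf,ng.h/mL,49.1,46.9,0.96
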