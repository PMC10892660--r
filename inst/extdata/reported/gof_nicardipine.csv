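species,study,parameter,unit,observed,predicted,ratio_printed
rat,po 15 mg/kg,Cmax,ng/mL,132,69.3,0.53
rat,po 15 mg/kg,t_half,h,5.76,2.96,0.51
rat,po 15 mg/kg,AUCinf,ng.h/mL,408,333,0.82
human,po 40 mg,Cmax,ng/mL,58.8,36.4,0.63
human,po 40 mg,t_half,h,2.80,3.44,1.23
human,po 40 mg,AUCinf,ng.h/mL,163,138,0.85
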