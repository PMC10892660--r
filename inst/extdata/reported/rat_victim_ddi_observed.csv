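parameter,unit,alone_mean,alone_sd,combo_mean,combo_sd,ratio_printed
Cmax,ng/mL,98.5,15.1,281,147,2.85
Tmax,h,0.417,0.129,0.464,0.094,NA
t_half,h,1.82,0.737,2.97,1.23,1.63
AUCinf,ng.h/mL,157,23.1,408,213,2.60
CL_F,L/h/kg,32.5,5.15,14.3,4.86,0.44
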