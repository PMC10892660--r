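species,source,parameter,unit,alone,combo,ratio_printed
rat,observed,Cmax,ng/mL,98.5,281,2.85
rat,observed,AUCinf,ng.h/mL,157,408,2.60
rat,predicted,Cmax,ng/mL,147,395,2.69
rat,predicted,AUCinf,ng.h/mL,193,490,2.54
human,predicted,Cmax,ng/mL,9.81,10.8,1.10
human,predicted,AUCinf,ng.h/mL,50.5,52.9,1.05
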