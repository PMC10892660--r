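quantity,value,unit
depletion_t_half_min,34.8,min
depletion_enzyme_conc,10,pmol CYP/mL
ic50_rlm_um,8.59,uM
ic50_hlm_um,2.08,uM
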