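species,enzyme,ref_conc_pmol_per_mg
rat,CYP3A2,101
human,CYP3A4,137
human,CYP3A5,16
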