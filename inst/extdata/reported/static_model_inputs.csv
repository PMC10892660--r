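species,perpetrator_cmax_ng_ml,fraction_unbound,molecular_weight_g_mol,ki_um
rat,69.3,0.084,479.59,0.39
human,36.4,0.01,479.59,0.06
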