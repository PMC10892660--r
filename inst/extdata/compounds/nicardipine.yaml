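# Nicardipine — calcium-channel blocker, competitive CYP3A inhibitor
# (perpetrator drug). Units are embedded in the keys.
# cellular_permeability is carried with its explicit unit (cm/s as printed);
# see the methods vignette for the unit discussion.
name: nicardipine
molecular_weight_g_mol: 479.59
lipophilicity_logd74: 4.6
pka: 8.1
compound_type: base
solubility_mg_per_ml: 7.9
solubility_ref_ph: 7
fraction_unbound:
  rat: 0.084
  human: 0.01
specific_intestinal_permeability_1e-6_cm_s: 1.15
cellular_permeability:
  value: 0.09
  unit: cm/s
clearance:
  - kind: total_hepatic_halflife
    species: rat
    hepatic_t_half_min: 0.62
  - kind: total_hepatic_halflife
    species: human
    hepatic_t_half_min: 4.5
formulations:
  - name: solution
    kind: solution
  - name: tablet
    kind: tablet
    dissolution_shape: 1.18
    dissolution_time_min: 5.59
inhibitions:
  - species: rat
    enzyme: CYP3A2
    ki_um: 0.39
    mechanism: competitive
  - species: human
    enzyme: CYP3A4
    ki_um: 0.06
    mechanism: competitive
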