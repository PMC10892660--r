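# Rat co-administration scenario: saxagliptin 5 mg/kg oral solution with
# nicardipine 15 mg/kg, single dose, 24 h.
victim: saxagliptin
perpetrator: nicardipine
species: rat
victim_dose: 5
perp_dose: 15
per_kg: true
route: oral
victim_formulation: solution
perp_formulation: solution
duration_h: 24
inhibitor_source: liver_intracellular_unbound
sensitivity_parameters:
  - victim.clint.CYP3A2
  - victim.fraction_unbound
  - perpetrator.ki.CYP3A2
seed: 1
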