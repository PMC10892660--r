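organ,volume_ml,flow_frac,f_vascular,f_interstitial,f_water,f_lipid,f_protein,cyp3a_expr
lung,1.2,1.0,0.26,0.19,0.81,0.016,0.13,0.005
heart,0.8,0.05,0.06,0.16,0.76,0.032,0.15,0
brain,1.4,0.02,0.04,0.18,0.78,0.10,0.08,0
muscle,101,0.28,0.04,0.12,0.76,0.026,0.19,0
adipose,17.5,0.07,0.02,0.14,0.15,0.80,0.03,0
skin,47.5,0.06,0.05,0.30,0.65,0.061,0.25,0
bone,18.2,0.12,0.04,0.10,0.44,0.074,0.20,0
liver,9.15,0.02,0.11,0.16,0.75,0.068,0.18,1
spleen,0.5,0.01,0.22,0.15,0.78,0.026,0.18,0
kidney,1.83,0.14,0.11,0.20,0.78,0.039,0.16,0.01
gut,6.75,0.13,0.03,0.19,0.75,0.049,0.15,0.07
gonads,0.63,0.005,0.04,0.14,0.80,0.028,0.15,0
rest,26.69,0.095,0.04,0.15,0.70,0.10,0.15,0
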