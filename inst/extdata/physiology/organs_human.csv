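organ,volume_ml,flow_frac,f_vascular,f_interstitial,f_water,f_lipid,f_protein,cyp3a_expr
lung,532,1.0,0.26,0.19,0.81,0.016,0.13,0.005
heart,330,0.04,0.06,0.16,0.76,0.032,0.15,0
brain,1450,0.12,0.04,0.18,0.78,0.10,0.08,0
muscle,28000,0.17,0.04,0.12,0.76,0.026,0.19,0
adipose,15000,0.05,0.02,0.14,0.15,0.80,0.03,0
skin,2600,0.06,0.05,0.30,0.65,0.061,0.25,0
bone,5500,0.05,0.04,0.10,0.44,0.074,0.20,0
liver,1800,0.065,0.11,0.16,0.75,0.068,0.18,1
spleen,180,0.03,0.22,0.15,0.78,0.026,0.18,0
kidney,310,0.19,0.11,0.20,0.78,0.039,0.16,0.01
gut,1200,0.15,0.03,0.19,0.75,0.049,0.15,0.07
gonads,35,0.001,0.04,0.14,0.80,0.028,0.15,0
rest,7463,0.074,0.04,0.15,0.70,0.10,0.15,0
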