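{
  "species": "human",
  "body_weight": 71,
  "total_plasma_volume": 3.1,
  "total_lymph_flow": 2.91,
  "uptake_clearance_per_L": 241,
  "organs": {
    "name": ["lung", "liver", "kidney", "heart", "spleen", "gut", "muscle", "skin", "adipose", "brain", "rest"],
    "plasma_volume": [0.15, 0.3, 0.06, 0.015, 0.03, 0.15, 0.4, 0.12, 0.08, 0.03, 0.15],
    "interstitial_volume": [0.3, 0.6, 0.2, 0.05, 0.05, 0.45, 6, 1.7, 2, 0.2, 1],
    "endosomal_volume": [0.002, 0.004, 0.001, 0.0003, 0.0005, 0.002, 0.006, 0.003, 0.002, 0.0005, 0.002],
    "cellular_volume": [0.7, 1.2, 0.25, 0.25, 0.15, 1, 24, 2.6, 11, 1.2, 3],
    "blood_flow": [430, 800, 550, 150, 80, 600, 380, 120, 110, 350, 250],
    "lymph_flow": [0.1, 0.8, 0.2, 0.05, 0.05, 0.5, 0.45, 0.3, 0.2, 0.01, 0.25],
    "fcrn_concentration": [1000, 1000, 1000, 1000, 1000, 1000, 1000, 1000, 1000, 1000, 1000],
    "reflection_sigma": [0.9, 0.85, 0.9, 0.95, 0.85, 0.9, 0.95, 0.95, 0.95, 0.99, 0.95],
    "small_pore_fraction": [0.95, 0.95, 0.95, 0.95, 0.95, 0.95, 0.95, 0.95, 0.95, 0.95, 0.95],
    "large_pore_fraction": [0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05],
    "expression_weight": [0.8, 0.6, 0.9, 0.6, 0.4, 0.6, 0.5, 0.6, 0.5, 0, 0.4]
  }
}
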