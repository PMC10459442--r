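{
  "species": "cynomolgus",
  "body_weight": 6.2,
  "total_plasma_volume": 0.270704225352113,
  "total_lymph_flow": 0.467458428332945,
  "uptake_clearance_per_L": 954,
  "organs": {
    "name": ["lung", "liver", "kidney", "heart", "spleen", "gut", "muscle", "skin", "adipose", "brain", "rest"],
    "plasma_volume": [0.0130985915492958, 0.0261971830985916, 0.00523943661971831, 0.00130985915492958, 0.00261971830985915, 0.0130985915492958, 0.0349295774647887, 0.0104788732394366, 0.00698591549295775, 0.00261971830985915, 0.0130985915492958],
    "interstitial_volume": [0.0261971830985916, 0.0523943661971831, 0.0174647887323944, 0.00436619718309859, 0.00436619718309859, 0.0392957746478873, 0.523943661971831, 0.148450704225352, 0.174647887323944, 0.0174647887323944, 0.0873239436619718],
    "endosomal_volume": [0.000174647887323944, 0.000349295774647887, 8.73239436619718e-05, 2.61971830985915e-05, 4.36619718309859e-05, 0.000174647887323944, 0.000523943661971831, 0.000261971830985915, 0.000174647887323944, 4.36619718309859e-05, 0.000174647887323944],
    "cellular_volume": [0.0611267605633803, 0.104788732394366, 0.021830985915493, 0.021830985915493, 0.0130985915492958, 0.0873239436619718, 2.09577464788732, 0.227042253521127, 0.96056338028169, 0.104788732394366, 0.261971830985916],
    "blood_flow": [69.074613121363, 128.510908132768, 88.3512493412782, 24.0957952748941, 12.8510908132768, 96.3831810995762, 61.0426813630649, 19.2766362199152, 17.6702498682556, 56.2235223080861, 40.1596587914901],
    "lymph_flow": [0.016063863516596, 0.128510908132768, 0.0321277270331921, 0.00803193175829802, 0.00803193175829802, 0.0803193175829802, 0.0722873858246822, 0.0481915905497881, 0.0321277270331921, 0.0016063863516596, 0.0401596587914901],
    "fcrn_concentration": [1000, 1000, 1000, 1000, 1000, 1000, 1000, 1000, 1000, 1000, 1000],
    "reflection_sigma": [0.9, 0.85, 0.9, 0.95, 0.85, 0.9, 0.95, 0.95, 0.95, 0.99, 0.95],
    "small_pore_fraction": [0.95, 0.95, 0.95, 0.95, 0.95, 0.95, 0.95, 0.95, 0.95, 0.95, 0.95],
    "large_pore_fraction": [0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05],
    "expression_weight": [0.8, 0.6, 0.9, 0.6, 0.4, 0.6, 0.5, 0.6, 0.5, 0, 0.4]
  }
}
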