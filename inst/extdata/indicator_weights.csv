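indicator,response,sd,mean,cv,weight
drying_time_min,Y1,32.64,207.35,0.16,0.18
color_difference,Y2,1.34,6.11,0.22,0.25
unit_energy_kJh_kg,Y3,1.38,9.63,0.14,0.16
polysaccharide_mg_g,Y4,2.95,21.9,0.13,0.15
rehydration_ratio,Y5,0.27,2.62,0.1,0.12
allantoin_ug_g,Y6,0.38,3.23,0.12,0.13
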