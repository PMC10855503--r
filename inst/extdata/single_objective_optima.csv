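indicator,response,direction,A,B,C,optimum
drying_time_min,Y1,minimize,63.41,4.58,81.04,136.37
color_difference,Y2,minimize,55.00,5.80,160.00,3.30
unit_energy_kJh_kg,Y3,minimize,58.16,4.00,80.00,6.75
polysaccharide_mg_g,Y4,maximize,57.68,5.18,159.69,26.23
rehydration_ratio,Y5,maximize,58.35,5.15,117.96,2.97
allantoin_ug_g,Y6,maximize,59.42,5.98,147.93,3.81
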