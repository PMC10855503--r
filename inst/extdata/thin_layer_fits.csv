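sweep,level,slope,intercept,r_squared,d_eff_printed,d_eff_recomputed
temperature,50,0.2375,0.1338,0.99051,8.55e-9,8.55e-9
temperature,55,0.2747,0.1072,0.99605,9.89e-8,9.89e-9
temperature,60,0.3275,0.175,0.98857,1.18e-8,1.18e-8
temperature,65,0.3673,0.1585,0.99189,1.32e-8,1.32e-8
temperature,70,0.4097,0.1467,0.99437,1.79e-8,1.47e-8
thickness,2,0.4978,0.1338,0.99276,1.79e-8,1.79e-8
thickness,4,0.3984,0.1072,0.98842,1.43e-8,1.43e-8
thickness,6,0.3275,0.175,0.98857,1.18e-8,1.18e-8
thickness,10,0.1644,0.1467,0.98028,5.92e-9,5.92e-9
distance,80,0.43398,0.1338,0.97689,1.56e-8,1.56e-8
distance,120,0.3275,0.175,0.98857,1.18e-8,1.18e-8
distance,160,0.29663,0.1585,0.98885,1.07e-8,1.07e-8
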