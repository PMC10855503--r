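response,term,coefficient
Y1,(Intercept),752.97794
Y1,A,-13.875
Y1,B,41.25
Y1,C,-4.17188
Y1,AC,0.09375
Y1,BC,-0.1875
Y2,(Intercept),12.00209
Y2,A,0.19375
Y2,B,-4.37902
Y2,C,-0.073732
Y2,B2,0.387001
Y2,C2,0.000194
Y3,(Intercept),212.90483
Y3,A,-7.1569
Y3,B,0.368625
Y3,C,0.027806
Y3,A2,0.061087
Y4,(Intercept),-447.54243
Y4,A,15.50538
Y4,B,6.04477
Y4,C,0.029875
Y4,A2,-0.132805
Y4,B2,-0.556283
Y5,(Intercept),-51.33316
Y5,A,1.77368
Y5,B,-0.095
Y5,C,0.035428
Y5,A2,-0.014947
Y5,C2,-0.000143
Y6,(Intercept),-62.2702
Y6,A,2.08336
Y6,B,1.26194
Y6,C,-0.005375
Y6,A2,-0.017584
Y6,B2,-0.111151
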