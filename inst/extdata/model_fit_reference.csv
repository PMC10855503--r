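model,response,r_squared,rmse
RSM,Y1,0.9667,5.9510
RSM,Y2,0.9794,0.1926
RSM,Y3,0.9568,0.2869
RSM,Y4,0.9502,0.6580
RSM,Y5,0.9766,0.0417
RSM,Y6,0.9754,0.0596
BP-GWO,Y1,0.9950,2.3005
BP-GWO,Y2,0.9942,0.1020
BP-GWO,Y3,0.9983,0.0573
BP-GWO,Y4,0.9976,0.1445
BP-GWO,Y5,0.9916,0.0250
BP-GWO,Y6,0.9933,0.0312
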