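set,A,B,C,Y1,Y2,Y3,Y4,Y5,Y6
predicted,63.57,4.27,91.39,133.71,7.26,8.54,20.73,2.84,3.69
experimental,64,4,91,128,7.54,8.61,19.94,2.76,3.63
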