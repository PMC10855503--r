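id,A,B,C,Y1,Y2,Y3,Y4,Y5,Y6
1,64.51,4.26,90.95,133.68,7.18,8.54,20.79,2.78,3.64
2,64.21,4.34,92.49,133.41,7.22,8.57,21.08,2.83,3.71
3,62.08,4.21,90.44,133.90,7.26,8.46,20.61,2.68,3.45
4,63.55,4.32,91.87,132.23,7.24,8.54,20.72,2.96,3.77
5,64.06,4.31,92.25,133.80,7.27,8.52,21.04,2.84,3.67
6,63.39,4.20,90.36,134.12,7.30,8.51,20.81,2.82,3.77
7,62.94,4.30,91.92,134.99,7.30,8.53,20.80,2.87,3.75
8,64.14,4.28,91.33,133.18,7.27,8.64,20.73,2.89,3.75
9,62.58,4.21,90.02,133.80,7.27,8.52,20.65,2.84,3.78
10,64.21,4.29,92.26,133.99,7.29,8.56,20.10,2.87,3.65
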