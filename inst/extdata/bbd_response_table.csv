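run,A,B,C,Y1,Y2,Y3,Y4,Y5,Y6
1,55,4,120,195,5.35,8.58,22.43,2.74,3
2,65,4,120,150,7.12,11.62,18.76,2.65,2.78
3,55,8,120,255,6.25,10.35,19.36,2.47,2.7
4,65,8,120,240,8.16,11.74,16.81,2.25,2.46
5,55,6,80,225,5.78,8.69,21.73,2.37,3.15
6,65,6,80,165,7.58,9.64,17.47,2.14,2.93
7,55,6,160,225,3.15,10.68,25.41,2.47,3.6
8,65,6,160,240,5.42,12.24,18.64,2.21,3.22
9,60,4,80,150,7.36,6.74,21.62,2.84,3.08
10,60,8,80,255,8.89,8.87,19.84,2.41,2.87
11,60,4,160,195,5.79,8.97,24.73,2.93,3.62
12,60,8,160,240,6.56,10.85,21.44,2.51,3.31
13,60,6,120,195,5.41,8.81,24.47,2.91,3.64
14,60,6,120,195,5.36,8.74,25.35,2.87,3.63
15,60,6,120,210,4.97,9.46,22.53,2.96,3.52
16,60,6,120,210,5.14,9.17,25.47,2.92,3.63
17,60,6,120,180,5.52,8.63,26.23,2.84,3.71
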