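label,sphere_size,contrast,background_variability
A,37,80.27,2.78
A,28,74.14,3.18
A,22,78.28,3.52
A,17,74.59,3.82
A,13,63.12,4.17
A,10,39.95,4.57
A,7,5.61,4.78
A,4,NA,NA
B,37,82.61,1.9
B,28,76.75,2.42
B,22,72.8,2.98
B,17,72.3,3.68
B,13,61.9,4.53
B,10,43.26,5.5
B,7,24.38,6.78
B,4,NA,NA
C,37,93.26,2.09
C,28,87.21,2.69
C,22,81.12,3.05
C,17,78.54,3.76
C,13,72.08,5.01
C,10,71.27,6.49
C,7,20.06,7.34
C,4,3.22,10.01
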