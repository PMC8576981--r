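contrast_pct,roi,ct,sd
0.5,insert,7.73,2.37
0.5,background_1,1.04,2.18
0.5,background_2,3.30,2.28
0.5,background_3,3.32,1.83
1.0,insert,11.16,2.03
1.0,background_1,1.61,2.08
1.0,background_2,1.57,1.98
1.0,background_3,1.04,2.18
1.5,insert,20.23,1.89
1.5,background_1,4.29,2.24
1.5,background_2,4.85,1.80
1.5,background_3,5.36,2.44
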