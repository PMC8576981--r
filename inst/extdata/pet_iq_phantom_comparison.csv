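label,sphere_size,contrast,background_variability
nim_petct,37,82.11,2.05
nim_petct,28,75.81,2.67
nim_petct,22,73.11,3.27
nim_petct,17,71.43,3.86
nim_petct,13,61.09,4.64
nim_petct,10,45.08,5.46
nim_petct,7,20.52,6.45
nim_petct,4,NA,NA
nema_iec,37,82.2,1.99
nema_iec,28,74.84,2.53
nema_iec,22,72.38,3.04
nema_iec,17,69.01,3.59
nema_iec,13,58.41,4.32
nema_iec,10,42.52,5.33
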