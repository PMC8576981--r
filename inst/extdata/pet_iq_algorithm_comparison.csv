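label,sphere_size,contrast,background_variability
OSEM_PSF_TOF,37,87.87,2.35
OSEM_PSF_TOF,28,79.99,2.99
OSEM_PSF_TOF,22,81.16,3.53
OSEM_PSF_TOF,17,79.17,4.12
OSEM_PSF_TOF,13,76.44,5.13
OSEM_PSF_TOF,10,53.81,6.03
OSEM_PSF_TOF,7,5.61,7.02
OSEM_PSF_TOF,4,NA,NA
OSEM_TOF,37,88.06,3.14
OSEM_TOF,28,79.88,3.61
OSEM_TOF,22,78.31,3.99
OSEM_TOF,17,69.63,4.63
OSEM_TOF,13,64.12,5.69
OSEM_TOF,10,52.27,6.89
OSEM_TOF,7,4.32,8.28
OSEM_TOF,4,NA,NA
OSEM_PSF,37,75.25,3.35
OSEM_PSF,28,66.51,3.83
OSEM_PSF,22,74.8,4.48
OSEM_PSF,17,69.53,5.29
OSEM_PSF,13,59.66,6.11
OSEM_PSF,10,30.3,6.89
OSEM_PSF,7,NA,NA
OSEM_PSF,4,NA,NA
OSEM,37,75.86,3.81
OSEM,28,66.52,4.24
OSEM,22,69.14,4.82
OSEM,17,62.48,5.6
OSEM,13,56.38,6.42
OSEM,10,31.41,7.33
OSEM,7,NA,NA
OSEM,4,NA,NA
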