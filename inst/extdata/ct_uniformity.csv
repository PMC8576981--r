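mode,roi,ct
background,c,4.51
background,1,6.1
background,2,5.15
background,3,6.46
background,4,6.58
boundary,c,4.51
boundary,1,6.21
boundary,2,5.77
boundary,3,4.88
boundary,4,5.78
water,c,4.51
water,1,3.74
water,2,2.88
water,3,3.2
water,4,2.66
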