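roi,sd
1,3.31
2,3.36
3,3.57
4,3.65
5,3.26
6,3.43
7,3.29
8,3.32
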