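table,label,residual_error
phantom_comparison,nim_petct,8.98
phantom_comparison,nema_iec,9.10
system_comparison,A,7.46
system_comparison,B,8.45
system_comparison,C,3.24
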