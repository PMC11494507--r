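variant,pH,k_mean,k_sd,rel_rate_printed
unmodified,6.0,0.6,0.01,1
unmodified,7.5,0.019,0.003,0.032
unmodified,8.0,0.013,0.001,0.022
C10_n1c,6.0,4.4e-5,1.7e-5,7.3e-5
C10_n1c,8.0,5.0e-5,4.0e-6,8.3e-5
C10_n1c_c5n,6.0,0.67,0.08,1.1
C10_n1c_c5n,7.5,0.06,0.01,0.1
C10_n1c_c5n,8.0,0.0158,0.0006,0.026
A63_n7c,6.0,5.1,0.4,8.5
A63_n7c,7.5,0.52,0.03,0.87
A63_n7c,8.0,0.38,0.06,0.63
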