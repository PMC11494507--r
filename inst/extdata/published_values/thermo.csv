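variant,dG_barrier,k_int_rel_calc,k_int_rel_expt,pka_soln,dpka_shift,pka_ribozyme,pka_apparent
unmodified,16.3,1.0,1.0,4.2,2.1,6.3,6.4
C10_n1c,30.3,1e-11,1e-4,11.4,5.2,16.6,NA
C10_n1c_c5n,15.7,2.7,1.1,3.7,2.9,6.6,6.5
A63_n7c,15.4,4.3,6.1,4.2,2.1,6.3,6.9
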