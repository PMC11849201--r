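dough,phi_w_eff,chi_eff,noh_v_eff,phi_flour
D_Ref,0.526,0.350,34.1,0.448
D_FOS,0.485,0.564,21.6,0.444
D_Myl,0.494,0.548,25.5,0.438
D_OFP,0.481,0.588,15.5,0.444
D_Myl_PDX,0.482,0.627,18.0,0.444
D_CLR,0.472,0.739,11.9,0.450
D_PDX,0.470,0.706,10.5,0.451
D_IQ,0.472,0.774,11.5,0.450
D_OFP_CLR,0.475,0.636,14.4,0.449
D_OFP_TEX,0.503,0.768,14.7,0.425
D_CLR_TEX,0.503,0.833,13.6,0.425
D_TEX,0.513,0.865,14.2,0.417
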