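name,structure_class,mw_g_mol,density_kg_m3,tg_dry_K,noh_s,noh_per_volume,chi_s
water,other,18,1000,139,2,111.1,NA
dextrose,glucan,180,1540,306,3.98,34.2,0.35
Myl,glucan,504,1550,389,7.81,23.2,0.60
FOS,fructan,605,1550,315,4.66,11.9,0.62
OFP,fructan,725,1550,328,5.16,11.0,0.65
CLR,fructan,1769,1550,362,7.24,6.3,0.84
PDX,glucan,2160,1550,353,5.51,4.4,0.80
IQ,fructan,2184,1550,372,8.09,5.7,0.89
TEX,fructan,3877,1550,421,23.18,9.3,1.0
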