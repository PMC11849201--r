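dough,protein_area_um2,n_junctions,n_endpoints,total_length_um,avg_length_um,lacunarity,branching_rate,endpoint_rate,protein_width_um
D_Ref,91909,480,418,14200,189,0.087,0.0052,0.0046,6.47
D_OFP,92412,470,510,13686,134,0.088,0.0051,0.0056,6.75
D_CLR,87774,429,500,13182,120,0.102,0.0049,0.0057,6.68
D_OFP_CLR,94785,502,517,14160,138,0.083,0.0053,0.0055,6.70
D_PDX,73117,299,541,10386,60,0.154,0.0041,0.0074,7.05
D_IQ,97692,609,465,15609,212,0.074,0.0062,0.0048,6.26
D_OFP_TEX,104725,678,429,16632,313,0.062,0.0065,0.0041,6.30
D_CLR_TEX,102554,690,397,16711,357,0.066,0.0067,0.0039,6.14
D_TEX,105060,726,381,17024,396,0.061,0.0069,0.0036,6.17
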