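species,gro_hr,time_gro_max,time_gro_min,r2_vpd,h_gro_yr,gro_yr
Abies alba,1.64,2,16,0.60,746,1817
Fagus sylvatica,0.94,1,13,0.81,606,1159
Fraxinus excelsior,2.02,2,17,0.72,572,1439
Picea abies,2.50,4,15,0.65,468,1507
Pinus sylvestris,2.29,6,15,0.50,301,795
Quercus petrea,1.14,4,14,0.94,540,1044
Quercus pubescens,1.69,6,14,0.68,280,656
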