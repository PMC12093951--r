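sample_id,day,ph,temperature_c,conductivity_uS_cm,tds_mg_L,calcium_mg_L_CaCO3,magnesium_mg_L,alkalinity_mg_L_CaCO3
w1,0,7.29,25,1000,,400,120,120
w2,12,7.30,25,,670,400,118,120
w3,14,8.00,25,1000,,380,115,110
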