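# Reference sampling-point values from the optimized 1 L column run
# (0.02 M NaHCO3, 10% CO2 switched to ambient air on day 12).
# Only reported reference values are included; unreported cells are blank.
day,od750,dilution_factor,cell_density,dry_weight_g_L,afdw_g_L,ph,precipitate_g_L,note
12,,1,,1.54,1.47,7.3,,end of 10% CO2 growth phase: dry weight and AFDW; pH during sparging
14,,1,,,1.52,8.6,0.59,two days after air switch: AFDW; risen pH; harvested precipitate mass
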