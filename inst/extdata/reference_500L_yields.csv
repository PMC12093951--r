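# Reference precipitate yields (as % of algal AFDW) at the sampling points of
# the 500 L photobioreactor run (5% CO2 to air on day 28, 0.02 M NaHCO3 on day 31).
# The yields at P4/P5 were reported only as unchanged from P3 and are omitted.
point,day,precipitate_yield_pct_afdw,note
P2,31,26.2,three days after air switch; day of NaHCO3 addition
P3,35,160.4,four days after NaHCO3 addition
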