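row,Pdp,Pe,Pus,Pdp_us,Popt
EAA,38.56,38.79,38.11,37.97,41.32
NEAA,53.05,52.33,52.68,55.04,57.26
TAA,91.61,91.12,90.79,93.01,98.58
EAA_over_NEAA_pct,73.00,74.00,72.00,69.00,72.00
EAA_over_TAA_pct,42.00,43.00,42.00,41.00,42.00
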