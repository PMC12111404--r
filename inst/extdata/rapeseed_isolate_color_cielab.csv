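parameter,Pdp,Pdp_sd,Pe,Pe_sd,Pus,Pus_sd,Pdp_us,Pdp_us_sd,Popt,Popt_sd
L,50.34,0.10,49.80,0.30,51.88,0.18,47.78,0.26,31.46,0.15
a,6.02,0.05,5.08,0.07,5.21,0.11,5.83,0.04,3.43,0.05
b,18.10,0.22,17.20,0.17,20.52,0.19,17.86,0.09,7.45,0.08
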