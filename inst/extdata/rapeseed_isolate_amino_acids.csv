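amino_acid,Pdp,Pdp_sd,Pe,Pe_sd,Pus,Pus_sd,Pdp_us,Pdp_us_sd,Popt,Popt_sd
Thr,4.55,0.07,5.20,0.04,4.94,0.08,4.56,0.07,4.97,0.11
Val,5.14,0.04,5.27,0.06,5.14,0.08,5.42,0.08,5.93,0.06
Met,3.10,0.04,2.58,0.06,2.58,0.08,3.02,0.06,3.35,0.06
Ile,4.31,0.08,4.58,0.07,4.35,0.04,4.21,0.03,4.44,0.10
Leu,6.71,0.03,7.10,0.07,6.73,0.08,6.83,0.04,7.57,0.08
Phe,4.83,0.04,5.14,0.07,4.96,0.03,4.65,0.04,4.96,0.07
Lys,6.95,0.03,6.21,0.10,6.65,0.13,6.71,0.03,7.24,0.11
His,2.97,0.04,2.71,0.06,2.76,0.08,2.57,0.04,2.86,0.07
Asp,8.42,0.03,9.21,0.11,8.92,0.10,9.07,0.03,9.47,0.14
Ser,4.94,0.11,5.23,0.03,5.20,0.10,5.12,0.07,5.55,0.04
Glu,13.68,0.07,13.11,0.11,13.19,0.14,15.20,0.07,16.79,0.14
Gly,4.21,0.07,4.16,0.03,4.10,0.06,4.61,0.03,5.14,0.10
Ala,4.04,0.04,4.07,0.06,4.05,0.03,4.35,0.08,5.01,0.06
Tyr,3.30,0.08,3.95,0.07,3.70,0.04,3.18,0.06,3.16,0.03
Arg,8.30,0.08,7.55,0.03,8.14,0.11,7.90,0.03,6.32,0.04
Pro,6.16,0.03,5.05,0.03,5.38,0.04,5.61,0.07,5.82,0.06
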