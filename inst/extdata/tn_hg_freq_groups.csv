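group,N,C-M130,E-M96,F-M89,G-M201,H-M69,H1-M52,H1a-M197,H2-Apt,J-M304,J2-M172,J2a1-M47,J2a3-M68,K-M9,L1-M27,L3-M357,O-M175,P-M45,Q-M242,R-M207,R1a1-M17,R2-M124,gene_diversity,gene_diversity_sd
HTF,338,8.88,0,53.25,0.59,6.21,9.76,0,2.07,0,8.28,0,0,0.3,5.03,1.18,0,0.3,1.18,0.59,1.48,0.89,0.687,0.025
HTC,105,1.9,0,7.62,0.95,0.95,25.71,0,0,0,2.86,0,13.33,0.95,5.71,0.95,0.95,0.95,3.81,3.81,14.29,15.24,0.867,0.016
HTK,127,1.57,0,23.62,0,7.09,42.52,0,0,0.79,1.57,0,0,1.57,9.45,0,0,0,0.79,1.57,1.57,7.87,0.748,0.028
SC,154,3.9,0,3.9,4.55,3.25,21.43,0,0.65,0.65,18.83,0,0.65,0,13.64,3.25,2.6,0,1.3,3.25,8.44,9.74,0.88,0.012
DLF,514,3.7,0.97,6.23,5.64,5.25,13.23,0.19,1.36,0,10.12,0,0.97,1.17,24.12,0.58,0.97,0.19,2.53,1.95,11.67,9.14,0.881,0.007
AW,307,3.26,0,5.21,2.28,5.21,19.22,0,1.95,0,11.07,0.33,0,0.33,12.05,1.63,0.65,0.65,0.65,0.98,20.2,14.33,0.87,0.007
BRH,135,3.7,0,0.74,4.44,0,13.33,0,2.96,0,6.67,0,0,1.48,13.33,0.74,1.48,0.74,0,5.93,42.22,2.22,0.779,0.03
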