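N,C-M130,E-M96,F-M89,G-M201,H-M69,H1-M52,H1a-M197,H2-Apt,J-M304,J2-M172,J2a1-M47,J2a3-M68,K-M9,L1-M27,L3-M357,O-M175,P-M45,Q-M242,R-M207,R1a1-M17,R2-M124,gene_diversity,gene_diversity_sd
1680,4.4,0.3,16.25,3.1,4.7,17.38,0.06,1.49,0.12,9.35,0.06,1.19,0.77,13.99,1.13,0.83,0.36,1.55,2.02,12.74,8.21,0.886,0.003
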