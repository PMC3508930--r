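population,group,N,C-M130,E-M96,F-M89,G-M201,H-M69,H1-M52,H1a-M197,H2-Apt,J-M304,J2-M172,J2a1-M47,J2a3-M68,K-M9,L1-M27,L3-M357,O-M175,P-M45,Q-M242,R-M207,R1a1-M17,R2-M124,gene_diversity,gene_diversity_sd
Paniya,HTF,72,15.28,0,75,0,0,0,0,0,0,0,0,0,1.39,1.39,0,0,0,1.39,1.39,2.78,1.39,0.418,0.067
Paliyan,HTF,95,10.53,0,55.79,2.11,2.11,11.58,0,0,0,9.47,0,0,0,2.11,3.16,0,0,0,0,3.16,0,0.659,0.049
Pulayar,HTF,63,1.59,0,57.14,0,6.35,11.11,0,0,0,15.87,0,0,0,1.59,1.59,0,1.59,3.17,0,0,0,0.64,0.06
Irula,HTF,80,6.25,0,36.25,0,18.75,7.5,0,8.75,0,1.25,0,0,0,16.25,0,0,0,1.25,1.25,0,2.5,0.799,0.028
Kadar,HTF,28,10.71,0,28.57,0,0,32.14,0,0,0,28.57,0,0,0,0,0,0,0,0,0,0,0,0.749,0.032
Kanikaran,HTC,17,0,0,11.76,5.88,0,29.41,0,0,0,5.88,0,0,0,23.53,0,0,0,5.88,5.88,5.88,5.88,0.875,0.058
Thoda,HTC,26,7.69,0,3.85,0,0,11.54,0,0,0,7.69,0,38.46,0,7.69,3.85,3.85,3.85,0,0,0,11.54,0.834,0.061
Kota,HTC,62,0,0,8.06,0,1.61,30.65,0,0,0,0,0,6.45,1.61,0,0,0,0,4.84,4.84,22.58,19.35,0.815,0.026
Betta Kurumba,HTK,17,0,0,58.82,0,0,11.76,0,0,0,0,0,0,0,17.65,0,0,0,0,0,5.88,5.88,0.64,0.116
Kattunaickan,HTK,46,2.17,0,21.74,0,17.39,41.3,0,0,2.17,4.35,0,0,0,0,0,0,0,2.17,4.35,0,4.35,0.761,0.044
Kurumba,HTK,35,2.86,0,11.43,0,2.86,65.71,0,0,0,0,0,0,2.86,5.71,0,0,0,0,0,2.86,5.71,0.561,0.096
Mullukurumba,HTK,29,0,0,20.69,0,0,34.48,0,0,0,0,0,0,3.45,24.14,0,0,0,0,0,0,17.24,0.776,0.036
Parayar NTN,SC,52,7.69,0,3.85,1.92,3.85,34.62,0,0,0,17.31,0,0,0,9.62,1.92,1.92,0,1.92,1.92,3.85,9.62,0.836,0.037
Parayar,SC,24,4.17,0,0,8.33,0,20.83,0,0,4.17,12.5,0,0,0,12.5,4.17,4.17,0,0,8.33,12.5,8.33,0.92,0.029
Pallar,SC,51,1.96,0,5.88,7.84,5.88,11.76,0,1.96,0,13.73,0,1.96,0,15.69,5.88,0,0,1.96,1.96,13.73,9.8,0.914,0.015
Paravar,SC,27,0,0,3.7,0,0,14.81,0,0,0,37.04,0,0,0,18.52,0,7.41,0,0,3.7,3.7,11.11,0.815,0.052
Yadhava,DLF,107,2.8,0,5.61,1.87,3.74,19.63,0,0,0,16.82,0,0,1.87,20.56,0,0.93,0,0,0.93,14.95,10.28,0.86,0.013
Vanniyar,DLF,21,0,0,9.52,4.76,0,4.76,0,0,0,14.29,0,9.52,0,28.57,0,0,0,0,0,14.29,14.29,0.876,0.043
Vanniyar NTN,DLF,96,7.29,1.04,8.33,3.13,3.13,13.54,0,3.13,0,7.29,0,2.08,0,23.96,2.08,2.08,0,0,2.08,11.46,9.38,0.889,0.016
Nadar TNV,DLF,59,0,0,8.47,8.47,11.86,15.25,0,1.69,0,5.08,0,0,0,28.81,0,0,0,3.39,0,6.78,10.17,0.861,0.025
Nadar Cape,DLF,98,4.08,4.08,5.1,9.18,7.14,7.14,0,1.02,0,9.18,0,1.02,0,23.47,0,1.02,1.02,9.18,1.02,12.24,4.08,0.895,0.015
Piramalai Kallar,DLF,53,9.43,0,5.66,3.77,3.77,16.98,0,1.89,0,1.89,0,0,1.89,47.17,1.89,0,0,0,0,1.89,3.77,0.745,0.055
Maravar,DLF,80,0,0,3.75,8.75,5,10,1.25,1.25,0,13.75,0,0,3.75,10,0,1.25,0,2.5,7.5,16.25,15,0.904,0.011
Valayar,AW,95,6.32,0,12.63,2.11,8.42,10.53,0,1.05,0,8.42,0,0,0,8.42,2.11,0,2.11,1.05,1.05,20,15.79,0.89,0.012
Tamil Jains,AW,100,4,0,2,2,3,22,0,3,0,11,0,0,1,9,2,2,0,1,0,18,20,0.862,0.015
Ezhava,AW,95,0,0,2.11,3.16,5.26,25.26,0,0,0,12.63,1.05,0,0,20,1.05,0,0,0,0,24.21,5.26,0.823,0.017
Mukkuvar,AW,17,0,0,0,0,0,17.65,0,11.76,0,17.65,0,0,0,5.88,0,0,0,0,11.76,11.76,23.53,0.89,0.04
Sourashtra,BRH,40,7.5,0,0,0,0,25,0,0,0,2.5,0,0,0,20,0,0,0,0,0,40,5,0.747,0.041
Brahacharanam,BRH,21,0,0,0,0,0,9.52,0,9.52,0,14.29,0,0,0,4.76,0,0,4.76,0,19.05,33.33,4.76,0.848,0.054
Iyengar,BRH,11,0,0,0,27.27,0,9.09,0,0,0,18.18,0,0,9.09,0,0,0,0,0,0,36.36,0,0.818,0.083
Vadama,BRH,63,3.17,0,1.59,4.76,0,7.94,0,3.17,0,4.76,0,0,1.59,14.29,1.59,3.17,0,0,6.35,47.62,0,0.746,0.052
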