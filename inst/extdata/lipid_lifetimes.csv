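dye,sample,temperature_c,chi2,alpha1_pct,tau1_ns,alpha2_pct,tau2_ns,mean_tau_ns
laurdan,DPPC,20,4.43,56,6.18,44,0.53,5.82
laurdan,PSM,20,1.29,57,4.96,43,2.50,4.28
laurdan,BSM,20,1.55,67,4.25,33,1.96,3.82
laurdan,DPPC/chol (6:4),20,4.53,60,5.75,40,0.61,5.41
laurdan,PSM/chol (2:1),20,3.31,69,5.58,31,0.61,5.34
laurdan,BSM/chol (2:1),20,1.50,90,4.73,10,2.52,4.61
laurdan,POPC/chol (2:1),20,1.45,100,4.35,NA,NA,4.35
laurdan,DOPC/BSM/chol (1:1:1),20,1.49,94,4.42,6,2.05,4.36
laurdan,DOPC/PSM/chol (1:1:1),20,1.73,81,4.43,19,0.70,4.30
laurdan,DOPC/chol (2:1),20,1.49,100,3.75,NA,NA,3.75
laurdan,DOPC,20,1.50,79,3.23,21,1.44,3.04
laurdan,POPC,20,2.69,79,3.28,21,0.43,3.19
laurdan,DPPC,50,4.26,100,2.89,NA,NA,2.89
laurdan,PSM,50,1.84,78,3.15,22,1.06,2.97
laurdan,BSM,50,2.15,68,2.79,32,1.03,2.53
laurdan,DPPC/chol (6:4),50,2.03,100,4.03,NA,NA,4.03
laurdan,PSM/chol (2:1),50,1.56,100,3.68,NA,NA,3.68
laurdan,BSM/chol (2:1),50,1.57,100,3.20,NA,NA,3.20
laurdan,POPC/chol (2:1),50,1.89,100,2.79,NA,NA,2.79
laurdan,DOPC/BSM/chol (1:1:1),50,1.63,38,3.09,62,2.92,2.99
laurdan,DOPC/PSM/chol (1:1:1),50,1.62,100,2.88,NA,NA,2.88
laurdan,DOPC/chol (2:1),50,1.66,100,2.48,NA,NA,2.48
laurdan,DOPC,50,1.84,65,2.81,35,0.83,2.54
laurdan,POPC,50,4.04,100,2.49,NA,NA,2.49
M-laurdan,DPPC,20,1.75,81,5.05,19,1.05,4.86
M-laurdan,PSM,20,1.36,58,4.69,42,2.14,4.06
M-laurdan,BSM,20,3.11,28,5.09,72,2.97,3.81
M-laurdan,DPPC/chol (6:4),20,5.17,60,4.80,40,0.67,4.45
M-laurdan,PSM/chol (2:1),20,2.66,68,4.55,32,0.51,4.36
M-laurdan,BSM/chol (2:1),20,1.29,61,4.83,39,2.90,4.29
M-laurdan,POPC/chol (2:1),20,1.50,100,3.98,NA,NA,3.98
M-laurdan,DOPC/BSM/chol (1:1:1),20,1.43,61,4.19,39,3.83,4.06
M-laurdan,DOPC/PSM/chol (1:1:1),20,2.50,82,4.06,18,2.12,3.85
M-laurdan,DOPC/chol (2:1),20,1.49,100,3.81,NA,NA,3.81
M-laurdan,DOPC,20,1.76,92,3.40,8,1.89,3.33
M-laurdan,POPC,20,5.99,64,3.42,36,0.64,3.16
M-laurdan,DPPC,50,1.31,100,3.28,NA,NA,3.28
M-laurdan,PSM,50,1.64,82,3.23,18,1.67,3.07
M-laurdan,BSM,50,3.07,83,2.82,17,1.86,2.70
M-laurdan,DPPC/chol (6:4),50,1.42,100,3.83,NA,NA,3.83
M-laurdan,PSM/chol (2:1),50,1.67,100,3.67,NA,NA,3.67
M-laurdan,BSM/chol (2:1),50,1.43,100,3.31,NA,NA,3.31
M-laurdan,POPC/chol (2:1),50,2.12,100,3.06,NA,NA,3.06
M-laurdan,DOPC/BSM/chol (1:1:1),50,1.65,100,3.29,NA,NA,3.29
M-laurdan,DOPC/PSM/chol (1:1:1),50,1.63,100,3.15,NA,NA,3.15
M-laurdan,DOPC/chol (2:1),50,1.41,59,3.33,41,2.78,3.12
M-laurdan,DOPC,50,1.41,65,3.37,35,2.01,3.04
M-laurdan,POPC,50,1.64,75,3.11,25,1.14,2.90
MoC-laurdan,DPPC,20,1.49,85,5.46,15,2.29,5.24
MoC-laurdan,PSM,20,1.50,42,3.46,58,1.82,2.77
MoC-laurdan,BSM,20,1.84,18,3.29,82,1.22,2.00
MoC-laurdan,DPPC/chol (6:4),20,1.37,85,4.91,15,1.62,4.73
MoC-laurdan,PSM/chol (2:1),20,2.25,43,5.09,57,1.90,4.03
MoC-laurdan,BSM/chol (2:1),20,1.33,41,4.12,59,2.04,3.26
MoC-laurdan,POPC/chol (2:1),20,1.59,80,3.39,20,1.22,3.21
MoC-laurdan,DOPC/BSM/chol (1:1:1),20,1.37,54,3.74,46,1.78,3.17
MoC-laurdan,DOPC/PSM/chol (1:1:1),20,2.12,62,3.59,38,1.50,3.16
MoC-laurdan,DOPC/chol (2:1),20,1.55,73,3.41,27,1.89,3.15
MoC-laurdan,DOPC,20,1.53,71,3.47,29,1.44,3.17
MoC-laurdan,POPC,20,1.88,82,3.19,18,1.56,3.03
MoC-laurdan,DPPC,50,1.38,18,4.89,82,2.61,3.28
MoC-laurdan,PSM,50,1.72,68,3.00,32,1.06,2.73
MoC-laurdan,BSM,50,2.54,34,2.44,66,0.87,1.80
MoC-laurdan,DPPC/chol (6:4),50,1.38,29,4.29,71,2.79,3.38
MoC-laurdan,PSM/chol (2:1),50,1.56,38,4.10,62,1.81,3.14
MoC-laurdan,BSM/chol (2:1),50,1.54,47,3.36,53,1.43,2.73
MoC-laurdan,POPC/chol (2:1),50,2.01,60,2.96,40,1.54,2.60
MoC-laurdan,DOPC/BSM/chol (1:1:1),50,1.75,51,3.18,49,1.19,2.66
MoC-laurdan,DOPC/PSM/chol (1:1:1),50,1.77,53,3.26,47,1.93,2.81
MoC-laurdan,DOPC/chol (2:1),50,1.95,72,3.04,28,1.69,2.80
MoC-laurdan,DOPC,50,1.70,79,3.25,21,1.50,3.06
MoC-laurdan,POPC,50,2.04,70,3.02,30,1.32,2.76
C-laurdan,DPPC,20,1.34,94,5.08,6,1.35,5.02
C-laurdan,PSM,20,1.48,42,3.64,58,1.59,2.87
C-laurdan,BSM,20,1.62,42,3.77,58,1.61,2.96
C-laurdan,DPPC/chol (6:4),20,1.66,85,4.83,15,1.12,4.69
C-laurdan,PSM/chol (2:1),20,4.04,59,5.39,41,0.61,5.05
C-laurdan,BSM/chol (2:1),20,1.34,83,4.65,17,2.49,4.44
C-laurdan,POPC/chol (2:1),20,1.63,90,3.62,10,1.66,3.53
C-laurdan,DOPC/BSM/chol (1:1:1),20,1.65,62,3.81,38,1.90,3.36
C-laurdan,DOPC/PSM/chol (1:1:1),20,2.51,58,4.30,42,2.01,3.72
C-laurdan,DOPC/chol (2:1),20,1.50,60,3.00,40,1.27,2.62
C-laurdan,DOPC,20,2.30,47,2.60,53,1.34,2.13
C-laurdan,POPC,20,2.17,63,2.54,37,1.48,2.26
C-laurdan,DPPC,50,2.39,26,2.90,74,1.34,2.01
C-laurdan,PSM,50,1.83,24,2.80,76,1.20,1.87
C-laurdan,BSM,50,2.35,35,2.46,65,0.93,1.83
C-laurdan,DPPC/chol (6:4),50,1.67,73,3.07,27,2.33,2.91
C-laurdan,PSM/chol (2:1),50,1.67,100,3.22,NA,NA,3.22
C-laurdan,BSM/chol (2:1),50,1.47,75,2.77,25,1.39,2.57
C-laurdan,POPC/chol (2:1),50,1.75,35,2.62,65,1.44,2.02
C-laurdan,DOPC/BSM/chol (1:1:1),50,1.50,17,3.34,83,1.59,2.12
C-laurdan,DOPC/PSM/chol (1:1:1),50,2.15,46,2.65,54,1.27,2.16
C-laurdan,DOPC/chol (2:1),50,1.99,22,2.53,78,1.16,1.69
C-laurdan,DOPC,50,2.35,16,2.95,84,1.01,1.70
C-laurdan,POPC,50,2.70,16,2.65,84,1.04,1.56
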