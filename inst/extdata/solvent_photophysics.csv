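dye,solvent,solvent_class,epsilon,phi,chi2,tau_ns,kr,knr,gp
laurdan,chloroform,nonpolar,4.8,0.61,1.53,2.78,0.22,0.14,0.48
laurdan,dichloromethane,polar-aprotic,9.1,0.67,1.99,2.97,0.23,0.11,0.48
laurdan,acetone,polar-aprotic,21.0,0.61,1.53,2.94,0.21,0.13,0.40
laurdan,acetonitrile,polar-aprotic,37.5,0.63,1.82,3.11,0.20,0.12,0.16
laurdan,dimethylformamide,polar-aprotic,38.0,0.67,1.81,3.19,0.21,0.10,0.04
laurdan,ethanol,polar-protic,24.6,0.68,1.81,3.05,0.22,0.10,-0.72
laurdan,methanol,polar-protic,33.0,0.53,1.80,2.64,0.20,0.18,-0.85
MoC-laurdan,chloroform,nonpolar,4.8,0.48,3.03,2.30,0.21,0.23,0.72
MoC-laurdan,dichloromethane,polar-aprotic,9.1,0.45,4.62,2.38,0.19,0.23,0.73
MoC-laurdan,acetone,polar-aprotic,21.0,0.41,1.81,2.36,0.17,0.25,0.71
MoC-laurdan,acetonitrile,polar-aprotic,37.5,0.48,1.50,2.83,0.17,0.18,0.61
MoC-laurdan,dimethylformamide,polar-aprotic,38.0,0.53,1.46,3.03,0.17,0.16,0.54
MoC-laurdan,ethanol,polar-protic,24.6,0.45,1.77,3.10,0.15,0.18,-0.20
MoC-laurdan,methanol,polar-protic,33.0,0.40,1.93,3.05,0.13,0.20,-0.44
M-laurdan,chloroform,nonpolar,4.8,0.58,6.74,1.95,0.30,0.22,0.68
M-laurdan,dichloromethane,polar-aprotic,9.1,0.48,2.70,1.95,0.25,0.27,0.74
M-laurdan,acetone,polar-aprotic,21.0,0.46,4.99,2.06,0.22,0.26,0.70
M-laurdan,acetonitrile,polar-aprotic,37.5,0.55,1.63,2.66,0.21,0.17,0.60
M-laurdan,dimethylformamide,polar-aprotic,38.0,0.62,1.68,2.83,0.22,0.13,0.51
M-laurdan,ethanol,polar-protic,24.6,0.55,2.48,2.85,0.19,0.16,-0.20
M-laurdan,methanol,polar-protic,33.0,0.38,2.38,2.38,0.16,0.26,-0.48
C-laurdan,chloroform,nonpolar,4.8,0.56,2.50,2.46,0.23,0.18,0.67
C-laurdan,dichloromethane,polar-aprotic,9.1,0.60,1.87,2.36,0.25,0.17,0.72
C-laurdan,acetone,polar-aprotic,21.0,0.13,1.87,2.29,0.05,0.38,0.57
C-laurdan,acetonitrile,polar-aprotic,37.5,0.10,2.43,2.27,0.04,0.40,0.43
C-laurdan,dimethylformamide,polar-aprotic,38.0,0.07,2.31,2.52,0.03,0.37,0.32
C-laurdan,ethanol,polar-protic,24.6,0.17,2.72,1.46,0.12,0.57,-0.61
C-laurdan,methanol,polar-protic,33.0,0.16,4.45,1.26,0.13,0.67,-0.74
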