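name,formula,molecular_weight,epsilon_360,phi,brightness
laurdan,C24H35NO,353.55,19500,0.61,11900
M-laurdan,C23H33NO,339.52,14100,0.58,8200
MoC-laurdan,C26H37NO3,411.59,11100,0.48,5300
C-laurdan,C25H35NO3,397.56,12200,0.56,6800
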