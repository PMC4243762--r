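name,epsilon,n,class
chloroform,4.8,1.4459,nonpolar
dichloromethane,9.1,1.4242,polar-aprotic
acetone,21.0,1.3588,polar-aprotic
acetonitrile,37.5,1.3442,polar-aprotic
dimethylformamide,38.0,1.4305,polar-aprotic
ethanol,24.6,1.3611,polar-protic
methanol,33.0,1.3288,polar-protic
water,80.1,1.3330,polar-protic
"1,4-dioxane",2.2,1.4224,nonpolar
cyclohexane,2.02,1.4266,nonpolar
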