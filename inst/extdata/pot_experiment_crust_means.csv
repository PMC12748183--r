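indicator,treatment,mean,sd
hardness,CK,0.35,0.02
hardness,DI,0.39,0.04
hardness,BA,0.40,0.03
hardness,DB,0.37,0.04
CR,CK,4.45,0.97
CR,DI,5.20,1.16
CR,BA,5.08,1.00
CR,DB,6.08,1.13
SWC,CK,11.44,0.19
SWC,DI,12.80,0.53
SWC,BA,13.08,0.49
SWC,DB,13.60,0.78
MWD,CK,1.68,0.09
MWD,DI,2.55,0.05
MWD,BA,2.15,0.08
MWD,DB,2.14,0.11
GMD,CK,0.79,0.04
GMD,DI,1.51,0.07
GMD,BA,1.20,0.05
GMD,DB,1.14,0.02
ws_MWD,CK,0.52,0.04
ws_MWD,DI,1.01,0.13
ws_MWD,BA,0.90,0.05
ws_MWD,DB,0.92,0.02
ws_GMD,CK,0.28,0.06
ws_GMD,DI,0.71,0.05
ws_GMD,BA,0.63,0.02
ws_GMD,DB,0.67,0.04
PAD,CK,43.24,14.82
PAD,DI,1.21,3.17
PAD,BA,8.37,1.92
PAD,DB,1.32,4.20
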