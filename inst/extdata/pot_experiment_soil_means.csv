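indicator,treatment,mean,sd
SWC,CK,14.27,0.77
SWC,DI,16.68,1.52
SWC,BA,16.87,0.97
SWC,DB,17.35,1.56
MWD,CK,1.89,0.06
MWD,DI,2.19,0.06
MWD,BA,2.31,0.11
MWD,DB,2.85,0.14
GMD,CK,1.10,0.05
GMD,DI,1.48,0.09
GMD,BA,1.69,0.08
GMD,DB,2.03,0.15
ws_MWD,CK,1.34,0.14
ws_MWD,DI,1.93,0.13
ws_MWD,BA,2.11,0.16
ws_MWD,DB,1.94,0.13
ws_GMD,CK,0.54,0.04
ws_GMD,DI,0.74,0.01
ws_GMD,BA,0.69,0.02
ws_GMD,DB,0.66,0.02
PAD,CK,19.60,2.13
PAD,DI,8.12,1.26
PAD,BA,16.74,0.42
PAD,DB,23.64,4.57
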