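indicator,ranch,control
DH,0.82,0.57
TE_mean,5.84,6.47
AC,0.22,0.48
CI,0.28,0.32
SOI,0.16,0.20
FCI,12.43,2.55
FML,3.29,2.23
TPP_TR,1.82,8.93
TPP_TB,17.27,85.22
TB_TST,0.018,0.005
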