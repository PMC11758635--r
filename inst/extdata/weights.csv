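indicator,weight
DH,0.133
AC,0.133
TE_mean,0.133
CI,0.114
SOI,0.114
FCI,0.114
FML,0.057
TPP_TR,0.1
TPP_TB,0.05
TB_TST,0.05
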