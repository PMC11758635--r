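indicator,poor,relatively_poor,medium,relatively_good,good,indicator_type
DH,0.073,0.414,0.540,0.631,1.209,Positive
TE_mean,2.920,6.800,9.400,11.500,13.236,Positive
AC,0.150,0.264,0.302,0.339,0.368,Positive
CI,0.100,0.204,0.265,0.310,0.348,Positive
SOI,0.009,0.144,0.180,0.210,0.271,Positive
FCI,0.650,2.800,4.980,9.400,14.700,Positive
FML,1.206,2.336,2.568,3.193,4.000,Positive
TPP_TR,15.509,3.522,2.572,1.922,1.346,Negative
TPP_TB,132.000,48.656,31.964,17.338,9.110,Negative
TB_TST,0.003,0.008,0.011,0.019,0.030,Negative
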