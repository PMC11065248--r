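condition,incidence,incidence_lo,incidence_hi,mortality,mortality_lo,mortality_hi,dalys,dalys_lo,dalys_hi
cvd,3417,3334,3512,163,140,190,3718,3299,4174
diabetes,1393,1327,1463,294,258,331,2088,1787,2402
asthma_copd,699,651,746,86,69,105,1856,1465,2270
breast_cancer,90,74,110,48,35,63,900,639,1190
colorectal_cancer,114,94,136,84,67,102,954,757,1165
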