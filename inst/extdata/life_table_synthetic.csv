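"age","mx_male","mx_female","ex_male","ex_female"
40,0.0031462,0.0019207,35.98,40.52
45,0.0048124,0.0029748,31.51,35.89
50,0.0073611,0.0046075,27.21,31.39
55,0.011259,0.0071363,23.14,27.06
60,0.017222,0.011053,19.34,22.96
65,0.026343,0.017119,15.85,19.12
70,0.040294,0.026514,12.73,15.6
75,0.061633,0.041066,10.01,12.46
80,0.094274,0.063605,7.72,9.73
85,0.1442,0.098513,5.87,7.44
90,0.22057,0.15258,4.43,5.58
95,0.33738,0.23632,3.32,4.11
100,0.51605,0.36602,1.94,2.73
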