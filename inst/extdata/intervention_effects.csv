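who_id,condition,d_incidence,d_mortality,d_dalys,d_dalys_lo,d_dalys_hi
1.4,cvd,-303,-14,-404,-431,-403
1.4,diabetes,0,0,0,0,0
1.4,asthma_copd,-11,-1,-29,-29,-16
1.4,breast_cancer,0,0,0,0,0
1.4,colorectal_cancer,0,0,0,0,0
2.11,cvd,-9,-1,-12,-15,-4
2.11,diabetes,-3,0,-4,-6,-3
2.11,asthma_copd,0,0,0,0,0
2.11,breast_cancer,0,0,0,0,0
2.11,colorectal_cancer,0,0,0,0,0
2.13,cvd,-14,-1,-19,-20,-10
2.13,diabetes,-4,-1,-5,-8,-5
2.13,asthma_copd,0,0,0,0,0
2.13,breast_cancer,0,0,-1,-2,0
2.13,colorectal_cancer,0,0,-1,-2,0
3.1,cvd,-11,-1,-15,-18,-5
3.1,diabetes,-5,-1,-9,-9,-5
3.1,asthma_copd,-3,0,-7,-13,-1
3.1,breast_cancer,0,0,-3,-6,0
3.1,colorectal_cancer,-1,0,-3,-7,0
3.2,cvd,-28,-1,-38,-54,-33
3.2,diabetes,-15,-3,-24,-30,-12
3.2,asthma_copd,-7,-1,-18,-27,-9
3.2,breast_cancer,-1,-1,-6,-7,-2
3.2,colorectal_cancer,-1,-1,-8,-12,-4
6.2,cvd,0,0,0,0,0
6.2,diabetes,0,0,0,0,0
6.2,asthma_copd,0,0,0,0,0
6.2,breast_cancer,0,-5,-87,-127,-59
6.2,colorectal_cancer,0,0,0,0,0
6.3,cvd,0,0,0,0,0
6.3,diabetes,0,0,0,0,0
6.3,asthma_copd,0,0,0,0,0
6.3,breast_cancer,0,0,0,0,0
6.3,colorectal_cancer,0,-14,-160,-177,-148
6.4,cvd,0,0,0,0,0
6.4,diabetes,0,0,0,0,0
6.4,asthma_copd,0,0,0,0,0
6.4,breast_cancer,0,-12,-217,-258,-180
6.4,colorectal_cancer,0,0,0,0,0
7.3,cvd,0,0,0,0,0
7.3,diabetes,0,0,0,0,0
7.3,asthma_copd,-33,-4,-90,-97,-85
7.3,breast_cancer,0,0,0,0,0
7.3,colorectal_cancer,0,0,0,0,0
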