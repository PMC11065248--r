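condition,disability_weight
cvd,0.08
diabetes,0.07
asthma_copd,0.19
breast_cancer,0.29
colorectal_cancer,0.29
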