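level,median_x_step1,median_x_step2,median_y_step1,median_y_step2,n
T9,3.94,2.95,8.89,5.64,15
T10,2.86,2.50,3.47,2.96,66
T11,2.56,2.50,3.09,2.50,139
T12,2.52,2.32,2.53,2.06,188
L1,2.16,1.97,2.11,1.84,194
L2,1.71,1.56,2.12,1.71,195
L3,1.52,1.59,1.79,1.44,195
L4,1.59,1.52,1.68,1.40,195
L5,2.01,1.86,2.21,2.05,195
S1,3.27,2.44,2.51,2.38,195
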