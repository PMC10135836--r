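day,male_mean,male_sd,n_male,female_mean,female_sd,n_female,p_reported
1,1.125607,0.167139,8,0.95094,0.086574,8,0.023633
2,1.023389,0.16627,8,0.95714,0.072835,8,0.326269
3,1.06362,0.123114,8,0.974016,0.177845,8,0.264056
4,1.087815,0.12767,8,0.943842,0.070731,8,0.017585
5,1.061307,0.119568,8,1.006839,0.154494,8,0.444491
6,1.117094,0.172387,8,0.959187,0.101615,8,0.047364
7,1.058761,0.148037,8,0.963327,0.115739,8,0.174494
8,1.066774,0.125547,8,0.990487,0.119059,8,0.232832
9,1.122262,0.112674,8,0.953107,0.124892,8,0.006125
10,1.083995,0.128271,8,0.928134,0.07559,8,0.012954
11,1.077437,0.120659,8,0.94658,0.076244,8,0.023521
12,1.131611,0.167438,8,0.961139,0.102673,8,0.030321
13,1.08715,0.095502,8,0.959394,0.091049,8,0.016
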