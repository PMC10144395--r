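outcome,coverage_pct,W_wealth_only,W_composite,AEG
BCG,94.0,0.013,0.031,0.146
DTP1,91.8,0.016,0.033,0.155
DTP2,87.4,0.026,0.05,0.206
DTP3,82.0,0.031,0.062,0.235
OPV1,92.5,0.014,0.029,0.122
OPV2,87.6,0.024,0.048,0.197
OPV3,81.6,0.03,0.063,0.239
MCV1,80.3,0.024,0.047,0.195
ZERO,3.3,-0.014,0.573,0.091
FULL,78.4,0.031,0.077,0.303
COMPLETE,84.5,0.028,0.067,0.28
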