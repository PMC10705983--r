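trial,water,total_solids,ash,fat,protein,total_sugars,firmness,consistency,viscosity_index,cohesivity
1,0.08,0.08,0.002,0.07,0.01,0.28,0.08,0.03,0.11,0.005
2,0.2,0.2,0.04,0.07,0.01,0.17,0.03,0.34,0.16,0.01
3,0.3,0.3,0.05,0.07,0.02,0.22,0.06,0.14,0.14,0.006
4,0.2,0.2,0.004,0.17,0.04,0.19,0.22,0.19,1.22,0.36
5,0.05,0.05,0.008,0.11,0.01,0.13,0.02,0.04,0.05,0.004
6,0.08,0.08,0.01,0.11,0.002,0.13,0.05,0.18,0.06,0.002
7,0.06,0.06,0.01,0.19,0.007,0.39,0.02,0.06,0.04,0.005
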