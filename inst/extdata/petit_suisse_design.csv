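trial,inulin_g_per_100g,xanthan_g_per_100g,water,total_solids,ash,fat,protein,total_sugars,firmness,consistency,viscosity_index,cohesivity
1,6,0.5,53.16,46.83,0.41,8.33,3.11,18.31,0.61,5.39,3.01,0.23
2,16,0.5,59.23,40.76,0.45,8.37,3.13,24.5,1.24,12.7,6.44,0.42
3,6,0.8,51.57,48.42,0.52,8.31,3.13,19.75,1.11,11.16,6.30,0.41
4,16,0.8,58.29,43.70,0.66,8.31,3.15,25.98,2.12,19.68,13,1.29
5,11,0.65,57.70,42.29,0.46,8.33,3.12,21.50,1.20,10.94,6.74,0.42
6,11,0.65,57.65,42.34,0.46,8.38,3.12,21.46,1.05,10.13,5.95,0.39
7,11,0.65,57.48,42.51,0.45,8.37,3.12,21.46,1.10,10.85,6.23,0.41
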