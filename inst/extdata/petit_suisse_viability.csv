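trial,day,cfu_per_ml
1,0,1.12e6
1,7,1.14e6
1,14,1.17e6
1,21,1.18e6
1,28,1.17e6
2,0,1.16e6
2,7,1.18e6
2,14,1.19e6
2,21,1.20e6
2,28,1.20e6
3,0,1.11e6
3,7,1.11e6
3,14,1.13e6
3,21,1.15e6
3,28,1.14e6
4,0,1.14e6
4,7,1.18e6
4,14,1.21e6
4,21,1.21e6
4,28,1.23e6
5,0,1.10e6
5,7,1.12e6
5,14,1.12e6
5,21,1.13e6
5,28,1.11e6
6,0,1.10e6
6,7,1.12e6
6,14,1.12e6
6,21,1.13e6
6,28,1.11e6
7,0,1.10e6
7,7,1.12e6
7,14,1.12e6
7,21,1.13e6
7,28,1.11e6
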