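B0_T,pool,intra_Hz,cross_Hz,auto_Hz
1.5,WP,1.175,0.061,0.165
3,WP,0.978,0.039,0.132
7,WP,0.718,0.016,0.095
1.5,MP,4.95,0.042,0.112
3,MP,3.72,0.027,0.090
7,MP,2.43,0.011,0.065
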