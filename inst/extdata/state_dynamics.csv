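index,morning_evening_r,evening_shift_sign
4,0.820,1
5,0.836,1
7,0.808,0
8,0.916,1
11,0.902,0
12,0.911,0
15,0.875,0
17,0.590,1
19,0.911,1
20,0.872,-1
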