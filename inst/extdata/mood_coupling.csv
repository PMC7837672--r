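index,valence_w,arousal_w
4,-0.40,-0.39
5,-0.41,-0.44
7,0.37,0.49
8,-0.43,-0.32
11,0.44,0.42
12,-0.52,-0.40
15,0.59,0.38
17,-0.47,-0.71
19,0.00,0.09
20,0.26,0.04
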