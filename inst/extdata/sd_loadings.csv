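index,inefficient,negative,calm,unhealthy,thrill,intentional
1,0.849,0.146,-0.055,0.129,-0.054,-0.009
2,0.821,-0.026,-0.044,-0.073,0.172,-0.080
3,0.765,0.289,0.017,0.318,-0.031,0.062
4,0.721,0.209,-0.337,0.135,-0.052,-0.229
5,0.580,0.534,-0.063,0.176,-0.091,0.069
6,0.580,0.210,-0.348,0.128,-0.149,-0.375
7,-0.539,-0.184,0.392,-0.229,0.015,0.272
8,0.133,0.867,-0.122,0.016,-0.072,0.075
9,0.249,0.837,-0.156,-0.056,0.040,0.090
10,-0.052,-0.682,0.527,-0.245,0.063,0.087
11,-0.015,-0.654,0.311,-0.280,-0.145,0.135
12,0.460,0.646,-0.063,0.113,-0.001,-0.035
13,0.227,0.094,-0.836,-0.106,-0.037,0.013
14,-0.071,-0.239,0.835,-0.216,-0.141,-0.071
15,-0.073,-0.444,0.597,-0.125,-0.132,0.138
16,0.139,0.118,-0.028,0.882,0.002,-0.047
17,0.373,0.122,-0.235,0.708,-0.139,0.163
18,0.024,-0.006,-0.166,-0.147,0.795,0.239
19,-0.039,0.029,0.045,0.065,0.784,-0.341
20,-0.178,0.070,0.011,0.077,-0.059,0.908
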