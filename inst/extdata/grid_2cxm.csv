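Fp,PS,ve,vp,T10,B1,S0
0.3,0.05,0.2,0.02,800,0.9,50
0.6,0.05,0.2,0.02,1000,1,50
0.3,0.15,0.2,0.02,1400,1.1,50
0.6,0.15,0.2,0.02,800,0.9,50
0.3,0.3,0.2,0.02,1000,1,50
0.6,0.3,0.2,0.02,1400,1.1,50
0.3,0.05,0.5,0.02,800,0.9,50
0.6,0.05,0.5,0.02,1000,1,50
0.3,0.15,0.5,0.02,1400,1.1,50
0.6,0.15,0.5,0.02,800,0.9,50
0.3,0.3,0.5,0.02,1000,1,50
0.6,0.3,0.5,0.02,1400,1.1,50
0.3,0.05,0.2,0.1,800,0.9,50
0.6,0.05,0.2,0.1,1000,1,50
0.3,0.15,0.2,0.1,1400,1.1,50
0.6,0.15,0.2,0.1,800,0.9,50
0.3,0.3,0.2,0.1,1000,1,50
0.6,0.3,0.2,0.1,1400,1.1,50
0.3,0.05,0.5,0.1,800,0.9,50
0.6,0.05,0.5,0.1,1000,1,50
0.3,0.15,0.5,0.1,1400,1.1,50
0.6,0.15,0.5,0.1,800,0.9,50
0.3,0.3,0.5,0.1,1000,1,50
0.6,0.3,0.5,0.1,1400,1.1,50
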