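Ktrans,ve,vp,T10,B1,S0
0,0.1,0.01,800,0.9,50
0.02,0.1,0.01,1000,1,50
0.05,0.1,0.01,1400,1.1,50
0.1,0.1,0.01,800,0.9,50
0.2,0.1,0.01,1000,1,50
0,0.3,0.01,1400,1.1,50
0.02,0.3,0.01,800,0.9,50
0.05,0.3,0.01,1000,1,50
0.1,0.3,0.01,1400,1.1,50
0.2,0.3,0.01,800,0.9,50
0,0.5,0.01,1000,1,50
0.02,0.5,0.01,1400,1.1,50
0.05,0.5,0.01,800,0.9,50
0.1,0.5,0.01,1000,1,50
0.2,0.5,0.01,1400,1.1,50
0,0.1,0.05,800,0.9,50
0.02,0.1,0.05,1000,1,50
0.05,0.1,0.05,1400,1.1,50
0.1,0.1,0.05,800,0.9,50
0.2,0.1,0.05,1000,1,50
0,0.3,0.05,1400,1.1,50
0.02,0.3,0.05,800,0.9,50
0.05,0.3,0.05,1000,1,50
0.1,0.3,0.05,1400,1.1,50
0.2,0.3,0.05,800,0.9,50
0,0.5,0.05,1000,1,50
0.02,0.5,0.05,1400,1.1,50
0.05,0.5,0.05,800,0.9,50
0.1,0.5,0.05,1000,1,50
0.2,0.5,0.05,1400,1.1,50
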