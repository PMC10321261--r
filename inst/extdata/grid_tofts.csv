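Ktrans,ve,T10,B1,S0
0.01,0.01,800,0.9,50
0.02,0.01,1000,1,50
0.05,0.01,1400,1.1,50
0.1,0.01,800,0.9,50
0.2,0.01,1000,1,50
0.35,0.01,1400,1.1,50
0.01,0.05,800,0.9,50
0.02,0.05,1000,1,50
0.05,0.05,1400,1.1,50
0.1,0.05,800,0.9,50
0.2,0.05,1000,1,50
0.35,0.05,1400,1.1,50
0.01,0.1,800,0.9,50
0.02,0.1,1000,1,50
0.05,0.1,1400,1.1,50
0.1,0.1,800,0.9,50
0.2,0.1,1000,1,50
0.35,0.1,1400,1.1,50
0.01,0.2,800,0.9,50
0.02,0.2,1000,1,50
0.05,0.2,1400,1.1,50
0.1,0.2,800,0.9,50
0.2,0.2,1000,1,50
0.35,0.2,1400,1.1,50
0.01,0.5,800,0.9,50
0.02,0.5,1000,1,50
0.05,0.5,1400,1.1,50
0.1,0.5,800,0.9,50
0.2,0.5,1000,1,50
0.35,0.5,1400,1.1,50
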