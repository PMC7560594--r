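res,name,element,x,y,z
DA,P,P,0.934,-0.156,-4.636
DA,OP1,O,1.781,0.996,-4.255
DA,OP2,O,-0.204,0.331,-5.665
DA,O5',O,0.241,-0.771,-3.320
DA,C5',C,-0.549,0.270,-2.744
DA,C4',C,-1.239,-0.251,-1.482
DA,O4',O,-0.267,-0.564,-0.458
DA,C3',C,-2.105,0.859,-0.835
DA,O3',O,-3.409,0.895,-1.418
DA,C2',C,-2.173,0.398,0.640
DA,C1',C,-0.965,-0.545,0.797
DA,N9,N,-0.078,-0.047,1.852
DA,C8,C,0.962,0.817,1.689
DA,N7,N,1.535,1.044,2.835
DA,C5,C,0.897,0.346,3.805
DA,C6,C,1.069,0.196,5.191
DA,N6,N,2.079,0.869,5.856
DA,N1,N,0.236,-0.603,5.850
DA,C2,C,-0.729,-1.249,5.224
DA,N3,N,-0.925,-1.144,3.927
DA,C4,C,-0.142,-0.368,3.184
DT,P,P,-3.968,-1.665,3.118
DT,OP1,O,-4.406,-2.599,4.208
DT,OP2,O,-4.901,-0.360,2.920
DT,O5',O,-2.493,-1.028,3.315
DT,C5',C,-2.005,-0.136,2.327
DT,C4',C,-0.611,0.328,2.728
DT,O4',O,0.247,-0.829,2.764
DT,C3',C,0.008,1.286,1.720
DT,O3',O,0.965,2.121,2.368
DT,C2',C,0.710,0.360,0.754
DT,C1',C,1.157,-0.778,1.657
DT,N1,N,1.164,-2.047,0.989
DT,C2,C,2.333,-2.544,0.374
DT,O2,O,3.410,-1.945,0.363
DT,N3,N,2.194,-3.793,-0.240
DT,C4,C,1.047,-4.570,-0.300
DT,O4,O,0.995,-5.663,-0.857
DT,C5,C,-0.143,-3.980,0.369
DT,C7,C,-1.420,-4.757,0.347
DT,C6,C,-0.013,-2.784,0.958
DG,P,P,-0.818,-0.321,4.935
DG,OP1,O,-1.774,0.766,4.630
DG,OP2,O,0.312,0.224,5.941
DG,O5',O,-0.126,-0.826,3.572
DG,C5',C,0.550,0.300,3.011
DG,C4',C,1.233,-0.113,1.706
DG,O4',O,0.253,-0.471,0.705
DG,C3',C,1.976,1.091,1.073
DG,O3',O,3.294,1.218,1.612
DG,C2',C,2.026,0.692,-0.421
DG,C1',C,0.897,-0.345,-0.573
DG,N9,N,-0.068,0.111,-1.575
DG,C8,C,-1.172,0.877,-1.341
DG,N7,N,-1.804,1.094,-2.458
DG,C5,C,-1.145,0.482,-3.472
DG,C6,C,-1.361,0.377,-4.866
DG,O6,O,-2.321,0.914,-5.391
DG,N1,N,-0.473,-0.327,-5.601
DG,C2,C,0.593,-0.928,-5.003
DG,N2,N,1.474,-1.643,-5.774
DG,N3,N,0.804,-0.839,-3.709
DG,C4,C,-0.027,-0.152,-2.917
DC,P,P,0.987,-0.017,-3.894
DC,OP1,O,1.802,1.099,-3.365
DC,OP2,O,-0.119,0.560,-4.910
DC,O5',O,0.255,-0.772,-2.674
DC,C5',C,-0.571,0.196,-2.027
DC,C4',C,-1.300,-0.459,-0.852
DC,O4',O,-0.363,-0.863,0.171
DC,C3',C,-2.206,0.569,-0.129
DC,O3',O,-3.488,0.649,-0.756
DC,C2',C,-2.322,-0.040,1.288
DC,C1',C,-1.106,-0.981,1.395
DC,N1,N,-0.267,-0.584,2.528
DC,C2,C,0.270,0.648,2.563
DC,O2,O,0.052,1.424,1.647
DC,N3,N,1.037,1.035,3.581
DC,C4,C,1.291,0.212,4.589
DC,N4,N,2.085,0.622,5.635
DC,C5,C,0.746,-1.088,4.580
DC,C6,C,-0.035,-1.465,3.541
LYS,N,N,1.422,1.796,0.198
LYS,CA,C,1.394,0.355,0.484
LYS,C,C,2.657,-0.284,-0.032
LYS,O,O,3.316,0.275,-0.876
LYS,CB,C,0.184,-0.278,-0.206
LYS,CG,C,-1.102,0.282,0.407
LYS,CD,C,-2.313,-0.351,-0.283
LYS,CE,C,-3.598,0.208,0.329
LYS,NZ,N,-4.761,-0.400,-0.332
ARG,N,N,-0.469,1.110,-0.993
ARG,CA,C,0.004,2.294,-1.708
ARG,C,C,-0.907,2.521,-2.901
ARG,O,O,-1.827,1.789,-3.242
ARG,CB,C,1.475,2.150,-2.127
ARG,CG,C,1.745,1.017,-3.130
ARG,CD,C,3.210,0.954,-3.557
ARG,NE,N,4.071,0.726,-2.421
ARG,CZ,C,5.469,0.624,-2.528
ARG,NH1,N,6.259,0.404,-1.405
ARG,NH2,N,6.078,0.744,-3.773
ALA,N,N,-0.966,0.493,1.500
ALA,CA,C,0.257,0.418,0.692
ALA,C,C,-0.094,0.017,-0.716
ALA,O,O,-1.056,-0.682,-0.923
ALA,CB,C,1.204,-0.620,1.296
GLY,N,N,1.931,0.090,-0.034
GLY,CA,C,0.761,-0.799,-0.008
GLY,C,C,-0.498,0.029,-0.005
GLY,O,O,-0.429,1.235,-0.023
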