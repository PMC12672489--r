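indicator,PC1,PC2,PC3,PC4,PC5,PC6,norm,communality,group
SM,0.598,-0.374,0.012,-0.017,-0.267,-0.083,1.640,0.575,1
BD,-0.552,0.229,0.125,0.25,0.214,0.021,1.503,0.481,1
TN,0.849,0.222,0.157,-0.029,0.051,-0.142,2.185,0.819,1
TP,0.042,-0.102,0.004,0.269,0.545,0.628,1.001,0.776,6
SOC,0.853,0.205,0.201,-0.115,-0.026,-0.126,2.201,0.839,1
MBC,0.845,0.117,-0.171,0.094,0.154,0.045,2.164,0.791,1
NH4,0.484,-0.178,-0.685,0.093,0.036,-0.010,1.579,0.745,3
NO3,0.162,0.608,-0.347,-0.248,0.363,0.135,1.234,0.728,2
MBN,0.85,0.102,-0.102,0.177,0.025,0.007,2.168,0.775,1
MBP,0.733,0.222,-0.166,-0.197,0.295,0.025,1.942,0.741,1
AP,0.547,-0.344,-0.163,-0.428,0.004,0.344,1.634,0.745,1
POD,0.375,-0.245,0.385,-0.617,-0.122,0.112,1.421,0.757,4
LAP,0.572,0.228,0.165,0.461,-0.182,0.057,1.635,0.655,1
BX,0.176,-0.173,-0.483,0.672,-0.321,0.026,1.286,0.85,4
ALP,0.895,-0.007,0.009,0.079,-0.053,-0.122,2.265,0.825,1
URE,0.578,-0.363,0.459,0.164,0.145,-0.128,1.709,0.74,1
CBH,0.142,-0.653,0.112,0.104,-0.136,0.444,1.162,0.686,2
NAG,0.037,-0.349,0.485,0.362,0.556,-0.184,1.194,0.833,5
ACP,0.255,0.473,0.465,0.225,-0.134,0.127,1.207,0.59,2
BG,0.023,0.514,0.317,0.072,-0.430,0.479,1.138,0.784,2
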