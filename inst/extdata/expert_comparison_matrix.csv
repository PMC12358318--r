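Criteria,E1,E2,E3,E4,E5,A1,A2.1,A2.2,A2.3,A3
E1,1.000,0.957,1.032,0.985,1.049,0.405,0.463,0.447,0.440,0.430
E2,1.045,1.000,1.078,1.029,1.107,0.423,0.480,0.467,0.460,0.449
E3,0.969,0.928,1.000,0.955,1.017,0.393,0.445,0.433,0.427,0.420
E4,1.1015,0.972,1.047,1.000,1.065,0.411,0.465,0.453,0.446,0.437
E5,0.953,0.903,0.983,0.939,1.000,0.386,0.436,0.426,0.419,0.412
A1,2.468,2.364,2.545,2.433,2.591,1.000,1.142,1.102,1.086,1.071
A2.1,2.160,2.083,2.247,2.151,2.294,0.876,1.000,0.962,0.943,0.930
A2.2,2.237,2.141,2.310,2.208,2.346,0.907,1.039,1.000,0.980,0.965
A2.3,2.272,2.174,2.343,2.243,2.387,0.921,1.060,1.020,1.000,0.985
A3,2.326,2.227,2.381,2.287,2.427,0.934,1.075,1.036,1.015,1.000
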