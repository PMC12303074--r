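wavelength_nm,HbO2,HHb,water,fat
600,1.715,7.868,0.00022,0.0008
650,0.197,2.010,0.00032,0.0006
700,0.155,0.962,0.00060,0.0007
750,0.278,0.753,0.00280,0.0011
800,0.437,0.408,0.00220,0.0009
850,0.567,0.370,0.00430,0.0010
900,0.642,0.408,0.00680,0.0060
950,0.645,0.370,0.03800,0.0035
1000,0.563,0.295,0.03600,0.0025
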