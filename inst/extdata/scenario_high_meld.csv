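id,meld,wait_days,D1,D2,D3,D4,D5,D6,D7,D8,D9,D10
R1,40,50,0.492,0.337,0.411,0.393,0.259,0.308,0.396,0.402,0.245,0.464
R2,39,120,0.525,0.440,0.519,0.500,0.351,0.407,0.428,0.509,0.334,0.497
R3,38,200,0.622,0.465,0.543,0.524,0.374,0.431,0.527,0.534,0.356,0.596
R4,35,310,0.610,0.528,0.605,0.658,0.510,0.494,0.515,0.666,0.491,0.584
R5,35,460,0.616,0.533,0.611,0.663,0.516,0.500,0.521,0.671,0.497,0.590
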