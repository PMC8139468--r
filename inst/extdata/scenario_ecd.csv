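id,meld,wait_days,D1,D2,D3,D4,D5,D6,D7,D8,D9,D10
R1,36,0,0.497,0.479,0.493,0.493,0.489,0.566,0.318,0.608,0.535,0.538
R2,28,0,0.535,0.441,0.531,0.455,0.527,0.603,0.352,0.571,0.573,0.575
R3,25,0,0.528,0.510,0.525,0.524,0.520,0.596,0.346,0.637,0.566,0.569
R4,23,0,0.553,0.536,0.550,0.549,0.546,0.621,0.369,0.660,0.591,0.593
R5,21,0,0.675,0.588,0.672,0.601,0.668,0.733,0.571,0.706,0.708,0.768
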