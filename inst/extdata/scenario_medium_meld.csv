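id,meld,wait_days,D1,D2,D3,D4,D5,D6,D7,D8,D9,D10
R1,27,0,0.379,0.540,0.453,0.523,0.325,0.459,0.442,0.359,0.547,0.585
R2,26,0,0.293,0.444,0.360,0.427,0.247,0.366,0.350,0.276,0.451,0.490
R3,25,0,0.410,0.572,0.485,0.554,0.354,0.491,0.474,0.389,0.578,0.616
R4,24,0,0.411,0.573,0.561,0.555,0.427,0.568,0.475,0.390,0.579,0.686
R5,23,0,0.522,0.677,0.667,0.661,0.612,0.673,0.586,0.500,0.683,0.773
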