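{
  "comment": "Published L1-logistic graft-survival model (5-year end-point): 49 coefficients after one-hot decomposition, in rank order by |weight|. The intercept was not published; 0 is a placeholder, overridable. The scaling block is SYNTHETIC: z-scoring moments of the package's default synthetic marginals (uniform over the admissible range: location = midpoint, scale = width/sqrt(12)), not the unpublished scaling of the original fit.",
  "intercept": 0.0,
  "intercept_published": false,
  "scaling": {
    "synthetic": true,
    "location": {"A-R": 50.5, "B-R": 43.95, "DW-R": 1758, "DA-R": 10, "ME-R": 40.5,
                 "A-D": 47, "B-D": 41.59, "CR-D": 12.535},
    "scale":    {"A-R": 18.7639, "B-R": 16.6922, "DW-R": 1015.0073, "DA-R": 5.7735,
                 "ME-R": 19.9186, "A-D": 25.9808, "B-D": 17.8003, "CR-D": 7.1967}
  },
  "weights": [
    {"rank": 1,  "name": "DW-R",     "weight": -1.916},
    {"rank": 2,  "name": "ME-R",     "weight": -1.450},
    {"rank": 3,  "name": "DA-R",     "weight": -1.176},
    {"rank": 4,  "name": "A-D",      "weight": -1.132},
    {"rank": 5,  "name": "A-R",      "weight": -0.703},
    {"rank": 6,  "name": "N-D",      "weight": -0.646},
    {"rank": 7,  "name": "MC-R",     "weight": -0.531},
    {"rank": 8,  "name": "DL-R(2)",  "weight": 0.524},
    {"rank": 9,  "name": "B-R",      "weight": 0.509},
    {"rank": 10, "name": "R-R",      "weight": -0.500},
    {"rank": 11, "name": "DI-R(2)",  "weight": 0.493},
    {"rank": 12, "name": "DI-R(3)",  "weight": 0.491},
    {"rank": 13, "name": "PM-R",     "weight": -0.445},
    {"rank": 14, "name": "DI-R(4)",  "weight": 0.445},
    {"rank": 15, "name": "COD-D(3)", "weight": 0.411},
    {"rank": 16, "name": "DL-R(0)",  "weight": 0.404},
    {"rank": 17, "name": "DI-R(5)",  "weight": 0.393},
    {"rank": 18, "name": "DL-R(4)",  "weight": 0.383},
    {"rank": 19, "name": "E-R(1)",   "weight": -0.368},
    {"rank": 20, "name": "COD-D(2)", "weight": 0.336},
    {"rank": 21, "name": "DL-R(3)",  "weight": 0.328},
    {"rank": 22, "name": "A-T",      "weight": 0.303},
    {"rank": 23, "name": "G-T(0)",   "weight": 0.286},
    {"rank": 24, "name": "COD-D(1)", "weight": 0.265},
    {"rank": 25, "name": "CR-D",     "weight": -0.251},
    {"rank": 26, "name": "E-D(0)",   "weight": 0.247},
    {"rank": 27, "name": "PU-R",     "weight": -0.240},
    {"rank": 28, "name": "E-R(2)",   "weight": 0.219},
    {"rank": 29, "name": "G-T(1)",   "weight": 0.215},
    {"rank": 30, "name": "COD-D(0)", "weight": 0.203},
    {"rank": 31, "name": "DL-R(1)",  "weight": 0.197},
    {"rank": 32, "name": "DI-R(0)",  "weight": 0.184},
    {"rank": 33, "name": "E-R(3)",   "weight": 0.179},
    {"rank": 34, "name": "G-T(2)",   "weight": 0.164},
    {"rank": 35, "name": "HD-D",     "weight": -0.160},
    {"rank": 36, "name": "CDC-D",    "weight": -0.150},
    {"rank": 37, "name": "E-D(3)",   "weight": -0.132},
    {"rank": 38, "name": "B-D",      "weight": -0.127},
    {"rank": 39, "name": "E-D(1)",   "weight": 0.112},
    {"rank": 40, "name": "E-R(0)",   "weight": 0.111},
    {"rank": 41, "name": "HE-D",     "weight": -0.109},
    {"rank": 42, "name": "T-R",      "weight": -0.088},
    {"rank": 43, "name": "HH-D",     "weight": -0.082},
    {"rank": 44, "name": "CA-R",     "weight": -0.063},
    {"rank": 45, "name": "C-R",      "weight": 0.057},
    {"rank": 46, "name": "E-D(2)",   "weight": 0.048},
    {"rank": 47, "name": "DI-R(1)",  "weight": 0.041},
    {"rank": 48, "name": "DL-R(5)",  "weight": 0.020},
    {"rank": 49, "name": "C-D",      "weight": 0.012}
  ]
}
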