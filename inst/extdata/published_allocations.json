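{
  "comment": "Published allocation decisions of the three simulation scenarios: 1-based recipient index chosen per donor column. The high-MELD scenario's waiting days are a SYNTHETIC fixture (strictly increasing R1..R5); only the fact that R5 waited longest was published.",
  "mediumMELD": [
    3,
    1,
    4,
    1,
    5,
    4,
    3,
    3,
    1,
    4
  ],
  "highMELD": [
    1,
    2,
    2,
    3,
    5,
    2,
    1,
    3,
    5,
    1
  ],
  "ecd": [
    2,
    1,
    4,
    1,
    4,
    2,
    5,
    1,
    2,
    5
  ]
}
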