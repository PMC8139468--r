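{
  "comment": "Cohort size and class split per graft-survival end-point in the source registry extract; the survival share is the calibration target of the synthetic generator.",
  "endpoints": {
    "3M": {"horizon_days": 91,   "non_survival": 2928, "survival": 34718, "total": 37646},
    "1Y": {"horizon_days": 365,  "non_survival": 5180, "survival": 28470, "total": 33650},
    "2Y": {"horizon_days": 730,  "non_survival": 6614, "survival": 23202, "total": 29816},
    "5Y": {"horizon_days": 1825, "non_survival": 8886, "survival": 11570, "total": 20456}
  }
}
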