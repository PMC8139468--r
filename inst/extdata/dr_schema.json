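{
  "comment": "Donor-recipient variable manifest: 28 variables with type and admissible range/levels. Short codes are the canonical column names of the cohort CSV dialect.",
  "fields": [
    {"name": "A-R",   "owner": "recipient", "label": "Age",                              "type": "numeric", "range": [18, 83]},
    {"name": "B-R",   "owner": "recipient", "label": "BMI",                              "type": "numeric", "range": [15.04, 72.86]},
    {"name": "CA-R",  "owner": "recipient", "label": "Cardiopathy",                      "type": "binary"},
    {"name": "C-R",   "owner": "recipient", "label": "CMV",                              "type": "binary"},
    {"name": "DW-R",  "owner": "recipient", "label": "Days in wait list",                "type": "numeric", "range": [0, 3516]},
    {"name": "DA-R",  "owner": "recipient", "label": "Days in ICU",                      "type": "numeric", "range": [0, 20]},
    {"name": "DI-R",  "owner": "recipient", "label": "Diagnosis at listing",             "type": "nominal", "levels": [0, 1, 2, 3, 4, 5],
     "level_labels": ["alcohol", "VHC", "VHB", "cholestasics", "FHF", "others"]},
    {"name": "DL-R",  "owner": "recipient", "label": "Diagnosis of the liver",           "type": "nominal", "levels": [0, 1, 2, 3, 4, 5],
     "level_labels": ["alcohol", "VHC", "VHB", "cholestasics", "FHF", "others"]},
    {"name": "E-R",   "owner": "recipient", "label": "Ethnicity",                        "type": "nominal", "levels": [0, 1, 2, 3],
     "level_labels": ["white", "black", "hispanic", "others"]},
    {"name": "MC-R",  "owner": "recipient", "label": "Medical condition",                "type": "binary",
     "level_labels": ["in ICU", "not hospitalised"]},
    {"name": "ME-R",  "owner": "recipient", "label": "MELD",                             "type": "numeric", "range": [6, 75]},
    {"name": "PM-R",  "owner": "recipient", "label": "Previous malignancy",              "type": "binary"},
    {"name": "PU-R",  "owner": "recipient", "label": "Previous upper abdominal surgery", "type": "binary"},
    {"name": "R-R",   "owner": "recipient", "label": "Portal vein risk factors",         "type": "binary"},
    {"name": "T-R",   "owner": "recipient", "label": "TIPSS",                            "type": "binary"},
    {"name": "A-D",   "owner": "donor",     "label": "Age",                              "type": "numeric", "range": [2, 92]},
    {"name": "B-D",   "owner": "donor",     "label": "BMI",                              "type": "numeric", "range": [10.76, 72.42]},
    {"name": "COD-D", "owner": "donor",     "label": "Cause of death",                   "type": "nominal", "levels": [0, 1, 2, 3],
     "level_labels": ["anoxia", "cerebrovascular/stroke", "head trauma", "CNS tumour"]},
    {"name": "CDC-D", "owner": "donor",     "label": "CDC risk HIV",                     "type": "binary"},
    {"name": "CR-D",  "owner": "donor",     "label": "Creatinine",                       "type": "numeric", "range": [0.07, 25]},
    {"name": "C-D",   "owner": "donor",     "label": "CMV",                              "type": "binary"},
    {"name": "E-D",   "owner": "donor",     "label": "Ethnicity",                        "type": "nominal", "levels": [0, 1, 2, 3],
     "level_labels": ["white", "black", "hispanic", "others"]},
    {"name": "HE-D",  "owner": "donor",     "label": "Hepatitis C",                      "type": "binary"},
    {"name": "HH-D",  "owner": "donor",     "label": "History of hypertension",          "type": "binary"},
    {"name": "HD-D",  "owner": "donor",     "label": "History of drugs",                 "type": "binary"},
    {"name": "N-D",   "owner": "donor",     "label": "Non-heart-beating donor",          "type": "binary"},
    {"name": "A-T",   "owner": "match",     "label": "ABO compatibility",                "type": "binary"},
    {"name": "G-T",   "owner": "match",     "label": "Gender compatibility",             "type": "nominal", "levels": [0, 1, 2],
     "level_labels": ["same gender", "donor male / recipient female", "donor female / recipient male"]}
  ]
}
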