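{
  "system": "ISSS (international) soil texture triangle",
  "version": "1.0",
  "units": "percent by mass",
  "tie_break": "rules are evaluated in order; the first rule whose conditions all hold assigns the class, so boundary compositions go to the earliest matching class",
  "rules": [
    {"class": "heavy clay",      "clay_ge": 65},
    {"class": "light clay",      "clay_ge": 45},
    {"class": "silty clay",      "clay_ge": 25, "silt_ge": 45},
    {"class": "sandy clay",      "clay_ge": 25, "sand_ge": 55},
    {"class": "light clay",      "clay_ge": 25},
    {"class": "silty clay loam", "clay_ge": 15, "silt_ge": 45},
    {"class": "sandy clay loam", "clay_ge": 15, "sand_ge": 55},
    {"class": "clay loam",       "clay_ge": 15},
    {"class": "silt loam",       "silt_ge": 45},
    {"class": "sand",            "sand_ge": 90},
    {"class": "loamy sand",      "sand_ge": 85},
    {"class": "sandy loam",      "sand_ge": 55},
    {"class": "loam"}
  ]
}
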