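{
  "levels": ["VeryLow", "Low", "Medium", "High", "VeryHigh"],
  "grades": ["Small", "Medium", "Large"],
  "weighting": {
    "rows": "reliability",
    "cols": "convincingness",
    "Large":  {"Large": "VeryHigh", "Medium": "High",   "Small": "Medium"},
    "Medium": {"Large": "High",     "Medium": "Medium", "Small": "Low"},
    "Small":  {"Large": "Medium",   "Medium": "Low",    "Small": "VeryLow"}
  },
  "combination": {
    "VeryHigh": {"VeryHigh": "VeryHigh", "High": "VeryHigh", "Medium": "VeryHigh", "Low": "VeryHigh", "VeryLow": "VeryHigh"},
    "High":     {"VeryHigh": "VeryHigh", "High": "VeryHigh", "Medium": "VeryHigh", "Low": "High",     "VeryLow": "High"},
    "Medium":   {"VeryHigh": "VeryHigh", "High": "VeryHigh", "Medium": "High",     "Low": "High",     "VeryLow": "Medium"},
    "Low":      {"VeryHigh": "VeryHigh", "High": "High",     "Medium": "High",     "Low": "Medium",   "VeryLow": "Medium"},
    "VeryLow":  {"VeryHigh": "VeryHigh", "High": "High",     "Medium": "Medium",   "Low": "Medium",   "VeryLow": "Low"}
  },
  "opposition": {
    "rows": "against",
    "cols": "for",
    "VeryHigh": {"VeryHigh": "0",   "High": "-H",  "Medium": "-VH", "Low": "-VH", "VeryLow": "-VH"},
    "High":     {"VeryHigh": "H",   "High": "0",   "Medium": "-M",  "Low": "-M",  "VeryLow": "-H"},
    "Medium":   {"VeryHigh": "VH",  "High": "M",   "Medium": "0",   "Low": "-VL", "VeryLow": "-L"},
    "Low":      {"VeryHigh": "VH",  "High": "M",   "Medium": "VL",  "Low": "0",   "VeryLow": "-VL"},
    "VeryLow":  {"VeryHigh": "VH",  "High": "H",   "Medium": "L",   "Low": "VL",  "VeryLow": "0"}
  }
}
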