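{
  "n_reports": 500,
  "demographics": {
    "Year": {"y1": 0.4, "y2": 0.3, "y3": 0.3},
    "Age": {"a1": 0.2, "a2": 0.3, "a3": 0.3, "a4": 0.2},
    "Gender": {"g1": 0.5, "g2": 0.5},
    "Weight": {"w1": 0.3, "w2": 0.4, "w3": 0.3},
    "Country": {"c1": 0.5, "c2": 0.3, "c3": 0.2}
  },
  "drug_probs": {"d1": 0.10, "d2": 0.15, "d3": 0.12, "d4": 0.08, "d5": 0.10,
                 "d6": 0.10, "d7": 0.05, "d8": 0.05, "d9": 0.08, "d10": 0.06},
  "symptom_probs": {"s1": 0.05, "s2": 0.08, "s3": 0.04, "s4": 0.06,
                    "s5": 0.05, "s6": 0.03, "s7": 0.05, "s8": 0.04},
  "associations": [
    {"drugs": ["d1"], "symptom": "s3", "rho": 6}
  ],
  "seed": 1
}
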