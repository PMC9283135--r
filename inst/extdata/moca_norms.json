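{
  "conti": {
    "label": "Conti normative dataset",
    "es0_cutoff": 17.36,
    "age_range": [60, 80],
    "age": {"transform": "identity", "coef": 0.175, "center": 70.08},
    "education": {"transform": "reciprocal", "coef": 24.3, "center": 0.126}
  },
  "santangelo": {
    "label": "Santangelo normative dataset",
    "es0_cutoff": 15.50,
    "age_range": [21, 95],
    "age": {"transform": "log10_100_minus_age", "coef": -4.228, "center": 1.58},
    "education": {"transform": "sqrt", "coef": -3.201, "center": 3.25}
  },
  "aiello": {
    "label": "Aiello normative dataset",
    "es0_cutoff": 18.58,
    "age_range": [21, 96],
    "age": {"transform": "cube", "coef": 0.000008, "center": 297697.184801},
    "education": {"transform": "log", "coef": -3.331407, "center": 2.325648}
  }
}
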