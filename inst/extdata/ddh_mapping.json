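{
  "model": "logistic",
  "intercept": 2.1494,
  "slope": -38.754,
  "note": "Distance-to-DDH mapping for the formula-2 intergenomic distance d2 = 1 - sum(identities)/sum(HSP length). Logistic calibration anchored at the published species boundary (70% DDH at d2 = 0.0336); ddh_percent = 100 / (1 + exp(-(intercept + slope * d2))). Replace intercept/slope to plug in other published coefficient sets; the package validates monotonicity only."
}
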