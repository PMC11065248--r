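{
  "_comment": "Replaceable coefficient fixtures for the five score families. Magnitudes are field-plausible defaults; calibration rescales every hazard to the burden targets, so these act as relative-risk shapes, not absolute risks.",
  "cvd": {
    "country_h0": {"jordan": 0.10, "lebanon": 0.08, "syria": 0.12},
    "b_age": 0.07,
    "b_male": 0.35,
    "b_sbp": 0.18,
    "b_tc": 0.15,
    "b_smoke": 0.55,
    "b_dm": 0.60,
    "case_fatality": 0.012
  },
  "diabetes": {
    "points_cut": [7, 12, 15, 21],
    "risk10": [0.01, 0.04, 0.17, 0.33, 0.50],
    "case_fatality": 0.010
  },
  "asthma_copd": {
    "h0": 0.004,
    "b_age": 0.02,
    "rr_prior_dx": 3.0,
    "rr_active_smoke": 1.5,
    "rr_secondhand": 1.2,
    "case_fatality": 0.006
  },
  "breast_cancer": {
    "h0": 0.0008,
    "b_age": 0.03,
    "rr_multiplier": 1.0,
    "case_fatality": 0.08
  },
  "colorectal_cancer": {
    "h0": 0.0009,
    "b_age": 0.045,
    "rr_male": 1.2,
    "rr_smoker": 1.3,
    "rr_obese": 1.2,
    "case_fatality": 0.12
  }
}
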