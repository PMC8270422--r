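{
  "name": "acarbose-cvd-trial treatment arm (synthetic stand-in)",
  "comment": "Synthetic arm specification for a Chinese prediabetes CVD-outcome trial: only the age distribution (mean 64.4, SD 8.2, protocol lower bound 50), female proportion (27%) and the HbA1c treatment effect (-0.05 from baseline mean 5.9%) are published anchors; every other field is an invented but plausible fill, stated explicitly as required.",
  "population": "prediabetes",
  "n_simulated": 100000,
  "follow_up": 5,
  "continuous": {
    "age": {"mean": 64.4, "sd": 8.2, "lower": 50},
    "hba1c": {"mean": 5.9, "sd": 0.4, "lower": 4.0, "upper": 6.4},
    "bmi": {"mean": 25.4, "sd": 3.2, "lower": 15},
    "sbp": {"mean": 131.0, "sd": 17.0, "lower": 80},
    "dbp": {"mean": 77.0, "sd": 10.0, "lower": 40},
    "hdl": {"mean": 1.2, "sd": 0.3, "lower": 0.4},
    "ldl": {"mean": 2.8, "sd": 0.9, "lower": 0.5},
    "triglycerides": {"mean": 1.7, "sd": 1.0, "lower": 0.3},
    "egfr": {"mean": 85.0, "sd": 20.0, "lower": 10},
    "hemoglobin": {"mean": 14.0, "sd": 1.5, "lower": 6},
    "wbc": {"mean": 6.8, "sd": 1.8, "lower": 2}
  },
  "binary": {
    "female": 0.27,
    "smoking_current": 0.26,
    "smoking_past": 0.10,
    "antihypertensive": 0.74,
    "statin": 0.40,
    "hist_ihd": 1.0,
    "hist_mi": 0.35,
    "hist_cerebrovascular": 0.05
  },
  "defaults": {
    "duration": 0
  },
  "treatment_effects": {
    "hba1c": {"absolute_change": 0.05, "baseline_mean": 5.9}
  },
  "endpoints": ["mortality", "diabetes_onset", "ihd", "mi",
                "renal_failure", "cerebrovascular"]
}
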