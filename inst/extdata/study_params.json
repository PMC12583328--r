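{
  "theatre_rate": 14.65,
  "stay_rate": 681,
  "equipment": [
    {
      "label": "laparoscopic tower",
      "arm": "LPS",
      "purchase_price": 140000,
      "depreciation_procedures": 1000,
      "annual_maintenance": 0
    },
    {
      "label": "robotic platform",
      "arm": "RBT",
      "purchase_price": 2000000,
      "depreciation_procedures": 1000,
      "annual_maintenance": 0
    }
  ],
  "scale": {
    "sessions_per_year": 300,
    "amortization_years": 10,
    "procedures_per_session": [1, 2, 3],
    "ratio_override": {"LPS": 0.59, "RBT": 0.88}
  },
  "discounts": {
    "equipment": [0, 0.1, 0.15, 0.2],
    "consumables": [0.3, 0.35]
  },
  "stats_alpha": 0.05,
  "reported_summaries": {
    "LPS": {
      "n": 75,
      "mean": {"theatre": 2356, "consumables": 1047, "equipment": 140, "stay": 1153},
      "sd": {"theatre": 880, "consumables": 314, "equipment": 0, "stay": 698},
      "total_sd": 1121
    },
    "RBT": {
      "n": 78,
      "mean": {"theatre": 2227, "consumables": 2057, "equipment": 2000, "stay": 768},
      "sd": {"theatre": 627, "consumables": 216, "equipment": 0, "stay": 317},
      "total_sd": 816
    }
  },
  "generator": {
    "LPS": {
      "n": 75,
      "age": [65.1, 10.5],
      "bmi": [29.1, 5.6],
      "theatre_minutes": [161, 60],
      "stay_days": [1.7, 1.02],
      "consumables": [1047, 314],
      "complication_prob": 0.04,
      "complexity_probs": [0.18666667, 0.61333333, 0.2]
    },
    "RBT": {
      "n": 78,
      "age": [65.4, 11.9],
      "bmi": [30.5, 7.4],
      "theatre_minutes": [152, 43],
      "stay_days": [1.12, 0.46],
      "consumables": [2057, 216],
      "complication_prob": 0.03846154,
      "complexity_probs": [0.16666667, 0.66666666, 0.16666667]
    }
  }
}
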