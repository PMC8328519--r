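{
  "name": "exp1",
  "screen": {"width": 1366, "height": 768},
  "n_items": 6,
  "calibration": {
    "item_vs_screen_center": 348,
    "item_vs_encoded_center": 267,
    "gist_vs_screen_center": 270,
    "min_pair_separation": 160,
    "outlier_offset": null
  },
  "generative": {
    "n_participants": 130,
    "delay_groups": {"24h": 44, "1week": 43, "1month": 43},
    "sessions": ["S1", "S2"],
    "schedule": [
      {"delay_group": "24h",    "session": "S1", "item_error_scale": 55,  "gist_error_scale": 40, "gist_pull": 0},
      {"delay_group": "24h",    "session": "S2", "item_error_scale": 70,  "gist_error_scale": 45, "gist_pull": 0},
      {"delay_group": "1week",  "session": "S1", "item_error_scale": 55,  "gist_error_scale": 40, "gist_pull": 0},
      {"delay_group": "1week",  "session": "S2", "item_error_scale": 95,  "gist_error_scale": 50, "gist_pull": 0.2},
      {"delay_group": "1month", "session": "S1", "item_error_scale": 55,  "gist_error_scale": 40, "gist_pull": 0},
      {"delay_group": "1month", "session": "S2", "item_error_scale": 130, "gist_error_scale": 60, "gist_pull": 0.8}
    ],
    "outlier_weight": null,
    "error_cv": 0.3,
    "swap_rate": 0.02,
    "pull_center": "auto",
    "seed": 4201
  }
}
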