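{
  "name": "exp2",
  "screen": {"width": 1366, "height": 768},
  "n_items": 8,
  "calibration": {
    "item_vs_screen_center": 386,
    "item_vs_encoded_center": 262,
    "gist_vs_screen_center": 223,
    "min_pair_separation": 100,
    "outlier_offset": 573
  },
  "generative": {
    "n_participants": 43,
    "delay_groups": null,
    "sessions": ["S1", "S2", "S3"],
    "schedule": [
      {"session": "S1", "item_error_scale": 35,  "gist_error_scale": 30, "gist_pull": 0},
      {"session": "S2", "item_error_scale": 55,  "gist_error_scale": 35, "gist_pull": 0.15},
      {"session": "S3", "item_error_scale": 110, "gist_error_scale": 45, "gist_pull": 0.8}
    ],
    "outlier_weight": 0.25,
    "error_cv": 0.3,
    "swap_rate": 0.02,
    "pull_center": "auto",
    "seed": 4201
  }
}
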