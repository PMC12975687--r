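{
  "name": "CCA",
  "diameter_mm": 15.3,
  "notch": "none",
  "point_spacing_mm": 2.55,
  "film_radius_mm": 13.95,
  "certified_cax": {
    "depth_mm": [0.83, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10],
    "normalized_dose": [1.35, 1.3, 1, 0.74, 0.52, 0.36, 0.23, 0.15, 0.09, 0.05, 0.03]
  },
  "certified_ratio_pct": 57,
  "certified_planar": [1.8015, 0.222754, 0.745852, 1.387261, 1.743612, 1.743612, 1.387261, 0.745852, 0.222754, 0.222754, 0.745852, 1.387261, 1.743612, 1.743612, 1.387261, 0.745852, 0.222754, 0.222754, 0.745852, 1.387261, 1.743612, 1.743612, 1.387261, 0.745852, 0.222754, 0.222754, 0.745852, 1.387261, 1.743612, 1.743612, 1.387261, 0.745852, 0.222754],
  "field": {
    "r05_mm": 11.5,
    "power": 3
  },
  "provenance": {
    "certified_cax": "certified",
    "certified_ratio_pct": "certified",
    "certified_planar": "synthetic",
    "planar_exposure": "15 min at 120.1 mGy/min (1.8015 Gy centre)"
  }
}
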