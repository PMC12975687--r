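{
  "name": "CIB",
  "diameter_mm": 20.2,
  "notch": "iris",
  "point_spacing_mm": 3.37,
  "film_radius_mm": 13.95,
  "certified_cax": {
    "depth_mm": [0.83, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10],
    "normalized_dose": [1.371, 1.3176, 1, 0.7286, 0.5028, 0.3416, 0.2133, 0.1361, 0.0795, 0.0429, 0.0251]
  },
  "certified_ratio_pct": 55.3,
  "certified_planar": [1.8015, 0.020703, 0.273759, 1.030825, 1.680073, 1.680073, 1.030825, 0.273759, 0.020703, 0.020703, 0.273759, 1.030825, 1.680073, 1.680073, 1.030825, 0.008213, 0.000621, 0.020703, 0.273759, 1.030825, 1.680073, 1.680073, 1.030825, 0.273759, 0.020703, 0.020703, 0.273759, 1.030825, 1.680073, 1.680073, 1.030825, 0.273759, 0.020703],
  "field": {
    "r05_mm": 11.8,
    "power": 3,
    "notch": {
      "r_start_mm": 7,
      "r_end_mm": 9.5,
      "angle_deg": 90,
      "half_width_deg": 25,
      "taper_deg": 10,
      "depth": 0.97
    }
  },
  "provenance": {
    "certified_cax": "synthetic",
    "certified_ratio_pct": "certified",
    "certified_planar": "synthetic",
    "planar_exposure": "15 min at 120.1 mGy/min (1.8015 Gy centre)"
  }
}
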