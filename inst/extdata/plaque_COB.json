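{
  "name": "COB",
  "diameter_mm": 19.8,
  "notch": "optic",
  "point_spacing_mm": 3.3,
  "film_radius_mm": 13.95,
  "certified_cax": {
    "depth_mm": [0.83, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10],
    "normalized_dose": [1.3354, 1.2877, 1, 0.7481, 0.5325, 0.3736, 0.2426, 0.1607, 0.0982, 0.0557, 0.0341]
  },
  "certified_ratio_pct": 58.1,
  "certified_planar": [1.8015, 0.019415, 0.266436, 1.022578, 1.678387, 1.678387, 1.022578, 0.266436, 0.019415, 0.019415, 0.266436, 1.022578, 1.678387, 1.678387, 1.022578, 0.266436, 0.000582, 0.019415, 0.266436, 1.022578, 1.678387, 1.678387, 1.022578, 0.266436, 0.019415, 0.019415, 0.266436, 1.022578, 1.678387, 1.678387, 1.022578, 0.266436, 0.019415],
  "field": {
    "r05_mm": 11.5,
    "power": 3,
    "notch": {
      "r_start_mm": 10.5,
      "r_end_mm": 12.5,
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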