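# Shared fixtures built in code.

# Inverse calibration with round parameters for arithmetic oracles.
example_inverse_curve <- function(sd_a = 0.1, sd_b = 1.0) {
  calibration_curve("inverse", a = 5, b = 40, n = 2.2,
                    sd_a = sd_a, sd_b = sd_b, dose_range_Gy = c(0.3, 2.4))
}

# Forward truth with parameters distinct from the defaults, for recovery
# tests where the fit must rediscover them.
example_forward_truth <- function() {
  calibration_curve("forward", a = 0.1, b = 0.025, n = 2.1)
}

uniform_scan <- function(value, n = 32, dpi = 300, bit_depth = 16L) {
  scan_image(matrix(value, n, n), dpi = dpi, bit_depth = bit_depth)
}

# Brute-force circular-ROI statistics: exhaustive loop over every pixel
# centre, independent of the bounding-box masking in roi_stats().
brute_force_roi <- function(pixels, dpi, cx_mm, cy_mm, diameter_mm) {
  pitch <- 25.4 / dpi
  r <- (diameter_mm / 2) / pitch
  vals <- c()
  for (i in seq_len(nrow(pixels))) {
    for (j in seq_len(ncol(pixels))) {
      dx <- (j - 1) - cx_mm / pitch
      dy <- (i - 1) - cy_mm / pitch
      if (dx^2 + dy^2 <= r^2 + 1e-12) vals <- c(vals, pixels[i, j])
    }
  }
  list(mean_pv = mean(vals),
       sd_pv = if (length(vals) > 1) stats::sd(vals) else 0,
       n_pixels = length(vals))
}
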