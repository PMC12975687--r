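test_that("reference CAX fit reproduces the certified table", {
  m <- plaque_model("CCA")
  fit <- make_reference_cax(m)
  expect_equal(evaluate_at_certified(fit, 2.0), 1.0)
  expect_equal(evaluate_at_certified(fit, 0.83), 1.35, tolerance = 0.01)
  expect_lt(fit$rms, 0.01)
})

test_that("planar fields peak at the centre and die off beyond the active area", {
  m <- plaque_model("CCA")
  f <- planar_dose_function(m, 1.8)
  expect_equal(f(0, 0), 1.8)
  rs <- seq(0.5, 12, by = 0.5)
  vals <- f(rs, 0)
  expect_true(all(diff(vals) < 0))
  # below 5% of centre dose beyond the 5% radius
  expect_lt(f(m$field$r05_mm + 0.5, 0), 0.05 * 1.8)
  expect_error(make_planar_field(m, 1.8, size_mm = -1), "nonpositive")
})

test_that("the iris notch pushes one intermediate grid point under the filter", {
  m <- plaque_model("CIB")
  g <- build_reference_grid(m)
  f <- planar_dose_function(m, 1.8)
  doses <- f(g$x_mm, g$y_mm)
  kept <- low_dose_filter(doses)
  below <- setdiff(region_point_set(g, "R2"), kept)
  expect_length(below, 1)
  expect_equal(g$axis[below], "y")
  expect_equal(abs(g$index[below]), 3)
})

test_that("forward model is the exact algebraic inverse of densitometry", {
  spec <- synthetic_spec("CCA", pixel_noise_sd = 0, seed = 1L)
  # zero dose, no noise: post equals pre exactly
  pair0 <- film_forward_model(matrix(0, 12, 12), spec)
  expect_identical(pair0$post$pixels, pair0$pre$pixels)

  # single known dose: measured netOD equals the true forward response
  d <- 1.5
  pair <- film_forward_model(matrix(d, 12, 12), spec)
  reading <- film_reading(p0 = pair$pre$pixels[1, 1],
                          p = pair$post$pixels[1, 1], p_bg = spec$p_bg)
  truth <- netod_from_dose(spec$true_curve, d)
  expect_equal(net_od(reading), truth, tolerance = 1e-4)  # quantization only
})

test_that("identical seeds give bit-identical scan pairs", {
  spec <- synthetic_spec("COB", seed = 77L)
  s1 <- simulate_scan_pair(spec, size_mm = 12)
  s2 <- simulate_scan_pair(spec, size_mm = 12)
  expect_identical(s1$pre$pixels, s2$pre$pixels)
  expect_identical(s1$post$pixels, s2$post$pixels)
  spec2 <- synthetic_spec("COB", seed = 78L)
  s3 <- simulate_scan_pair(spec2, size_mm = 12)
  expect_false(identical(s3$post$pixels, s1$post$pixels))
})

test_that("scan pairs and sidecar files land on disk", {
  spec <- synthetic_spec("CCA", seed = 5L)
  dir <- withr::local_tempdir()
  sim <- simulate_scan_pair(spec, size_mm = 12, out_dir = dir)
  expect_true(all(file.exists(file.path(dir, c("pre.tif", "post.tif",
                                               "truth_dose.csv",
                                               "spec.json")))))
  back <- read_scan(file.path(dir, "post.tif"), dpi = spec$dpi)
  expect_identical(back$pixels, sim$post$pixels)
  truth <- utils::read.csv(file.path(dir, "truth_dose.csv"))
  expect_equal(truth$truth_dose_Gy, sim$truth)
})

test_that("noise-free recovery is limited only by quantization and the family floor", {
  spec <- synthetic_spec("CCA", pixel_noise_sd = 0, seed = 1L)
  doses <- dose_schedule()$dose_Gy
  curve <- fit_inverse(netod_from_dose(spec$true_curve, doses), doses)
  test_doses <- seq(0.3, 2.4, by = 0.3)
  pair <- film_forward_model(matrix(test_doses, nrow = 1), spec)
  for (i in seq_along(test_doses)) {
    reading <- film_reading(pair$pre$pixels[1, i], pair$post$pixels[1, i],
                            p_bg = spec$p_bg)
    d_hat <- dose_from_netod(curve, net_od(reading), warn_range = FALSE)
    # 16-bit quantization alone moves the converted dose by < 0.1% ...
    d_exact <- dose_from_netod(
      curve, netod_from_dose(spec$true_curve, test_doses[i]),
      warn_range = FALSE)
    expect_lt(abs(d_hat - d_exact) / test_doses[i], 0.001)
    # ... and the total error including the irreducible inverse-family
    # mismatch stays under 1%
    expect_lt(abs(d_hat - test_doses[i]) / test_doses[i], 0.01)
  }
})

test_that("dose-recovery error shrinks as pixel noise vanishes", {
  m <- plaque_model("CCA")
  doses <- dose_schedule()$dose_Gy
  pitch <- 25.4 / 300
  npx <- floor(4 / pitch) + 1L
  c_mm <- (npx - 1) / 2 * pitch
  err_at_noise <- function(noise_sd, seed) {
    spec <- synthetic_spec(m, pixel_noise_sd = noise_sd, seed = seed)
    curve <- fit_inverse(netod_from_dose(spec$true_curve, doses), doses)
    pair <- film_forward_model(matrix(1.5, npx, npx), spec)
    roi <- roi_circle(c_mm, c_mm, 1)
    reading <- reading_from_rois(roi_stats(pair$pre, roi),
                                 roi_stats(pair$post, roi),
                                 p_bg = spec$p_bg)
    abs(dose_from_netod(curve, net_od(reading), warn_range = FALSE) - 1.5)
  }
  seeds <- 1:50
  e_hi <- mean(vapply(seeds, function(s) err_at_noise(400, s), numeric(1)))
  e_mid <- mean(vapply(seeds, function(s) err_at_noise(100, s), numeric(1)))
  e_lo <- mean(vapply(seeds, function(s) err_at_noise(10, s), numeric(1)))
  expect_lt(e_mid, e_hi)
  expect_lt(e_lo, e_mid)
})

test_that("simulated calibration series feeds the fit back to truth", {
  spec <- synthetic_spec("CCA", seed = 31L)
  cal <- simulate_calibration(spec)
  expect_equal(cal$dose_Gy[1], 0)
  expect_equal(cal$delta_netod[1], 0)
  expect_true(all(diff(cal$delta_netod) > 0))
  curve <- fit_inverse(cal$delta_netod, cal$dose_Gy)
  expect_gte(curve$r2, 0.999)
  # converting the true response of an independent dose lands near truth
  x15 <- netod_from_dose(spec$true_curve, 1.5)
  expect_lt(abs(dose_from_netod(curve, x15, warn_range = FALSE) - 1.5) / 1.5,
            0.02)
})

test_that("saturating pixel levels are refused", {
  sat_curve <- calibration_curve("forward", a = 3, b = 1, n = 2)
  spec <- synthetic_spec("CCA", true_curve = sat_curve, p0_mean = 40000,
                         p_bg = 39999, pixel_noise_sd = 0)
  expect_error(film_forward_model(matrix(2, 4, 4), spec), "saturated")
})
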