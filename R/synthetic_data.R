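#' Synthetic measurement specification
#'
#' Fixes every parameter of the synthetic scan generator: the plaque
#' model, the true forward film response used as physical ground truth,
#' pixel levels, additive Gaussian pixel noise, scanner geometry and the
#' random seed. One seed fixes all randomness, so identical specs produce
#' bit-identical scan pairs.
#'
#' Defaults emulate the reference measurement conditions: 300 dpi 16-bit
#' reflection scans, a 15-min exposure at the decay-corrected
#' 120.1 mGy/min rate, pre-irradiation pixel level 40000 over a 1000
#' background, and pixel noise of 200 (0.5% of the pre-irradiation level).
#'
#' @param model A [plaque_model()] or model name.
#' @param true_curve Forward [calibration_curve()] acting as the physical
#'   dose response; default [default_true_response()].
#' @param p0_mean Pre-irradiation mean pixel level.
#' @param p_bg Background pixel level (`p0_mean > p_bg`).
#' @param pixel_noise_sd Additive Gaussian pixel noise SD (>= 0).
#' @param dpi Scan resolution.
#' @param bit_depth Scanner bit depth.
#' @param seed Integer seed fixing all randomness.
#' @param exposure_minutes Irradiation time for planar fields.
#' @param dose_rate_mGy_per_min Decay-corrected dose rate.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(model = "CCA", true_curve = default_true_response(),
                           p0_mean = 40000, p_bg = 1000,
                           pixel_noise_sd = 200, dpi = 300, bit_depth = 16L,
                           seed = 1L, exposure_minutes = 15,
                           dose_rate_mGy_per_min = 120.1) {
  if (is.character(model)) model <- plaque_model(model)
  stopifnot(inherits(model, "plaque_model"),
            inherits(true_curve, "calibration_curve"),
            true_curve$form == "forward",
            p0_mean > p_bg, pixel_noise_sd >= 0)
  structure(
    list(model = model, true_curve = true_curve, p0_mean = p0_mean,
         p_bg = p_bg, pixel_noise_sd = pixel_noise_sd, dpi = dpi,
         bit_depth = as.integer(bit_depth), seed = as.integer(seed),
         exposure_minutes = exposure_minutes,
         dose_rate_mGy_per_min = dose_rate_mGy_per_min),
    class = "synthetic_spec"
  )
}

#' Default true forward film response
#'
#' The fixed ground-truth dose response of the synthetic film:
#' `dnetOD = 0.08*D + 0.02*D^1.8`. Chosen to give delta-netOD around
#' 0.03-0.29 over the 0.3-2.4 Gy calibration window, the working range of
#' reflection-mode radiochromic densitometry. The analysis pipeline never
#' sees these parameters; its inverse fit is a genuine estimation problem
#' in a different parameterization.
#'
#' @return A forward [calibration_curve()].
#' @export
default_true_response <- function() {
  calibration_curve("forward", a = 0.08, b = 0.02, n = 1.8,
                    dose_range_Gy = c(0, Inf))
}

#' Quartic reference fit of a model's certified depth-dose table
#'
#' Least-squares quartic through the 11 certified (depth, normalized dose)
#' points of a plaque model, normalized at 2 mm. The fit reproduces the
#' certified values to about the table's printed precision (residual RMS
#' below 0.01 normalized units).
#'
#' @param model A [plaque_model()].
#' @return A `quartic_fit` object from [fit_quartic()].
#' @export
make_reference_cax <- function(model) {
  stopifnot(inherits(model, "plaque_model"))
  cax <- model$certified_cax
  if (is.null(cax)) stop("model has no certified CAX table")
  fit_quartic(cax$depth_mm, cax$normalized_dose, normalization_depth_mm = 2)
}

#' Analytic planar dose field of a plaque model
#'
#' Returns the dose-field function `f(x_mm, y_mm)` used by the synthetic
#' generator: a radially symmetric super-exponential fall-off
#' `exp(-ln(20) * (r/r05)^p)` (so the field crosses 5% of its central
#' value exactly at radius `r05`), multiplied for notched models by a
#' notch attenuation sector that ramps in radially and angularly. The
#' per-model shape parameters live in the model definition; they are
#' chosen so that the 5%-of-maximum exclusion filter reproduces the
#' characteristic kept-point patterns (all 33 points for CCA; the
#' outermost ring excluded for COB/CIB; one additional intermediate point
#' under the CIB iris notch).
#'
#' @param model A [plaque_model()].
#' @param center_dose_Gy Dose at the field centre (> 0).
#' @return A vectorized function of `(x_mm, y_mm)` returning Gy.
#' @export
planar_dose_function <- function(model, center_dose_Gy) {
  stopifnot(inherits(model, "plaque_model"), center_dose_Gy > 0)
  fld <- model$field
  function(x_mm, y_mm) {
    r <- sqrt(x_mm^2 + y_mm^2)
    dose <- center_dose_Gy * exp(-log(20) * (r / fld$r05_mm)^fld$power)
    if (model$notch != "none") {
      nt <- fld$notch
      g <- pmin(1, pmax(0, (r - nt$r_start_mm) /
                             (nt$r_end_mm - nt$r_start_mm)))
      theta <- atan2(y_mm, x_mm)
      theta0 <- nt$angle_deg * pi / 180
      dtheta <- abs(atan2(sin(theta - theta0), cos(theta - theta0)))
      h <- pmin(1, pmax(0, (nt$half_width_deg * pi / 180 - dtheta) /
                             (nt$taper_deg * pi / 180)))
      dose <- dose * (1 - nt$depth * g * h)
    }
    dose
  }
}

#' Rasterize a plaque's planar dose field
#'
#' Samples [planar_dose_function()] on a square pixel raster at the scan
#' resolution, centred on the field centre.
#'
#' @param model A [plaque_model()].
#' @param center_dose_Gy Dose at the centre (> 0).
#' @param size_mm Side length of the square map (> 0).
#' @param dpi Raster resolution (defaults to the 300 dpi scan protocol).
#' @return An object of class `dose_map`: list with `dose` (matrix, Gy,
#'   rows = y), `dpi`, and `center_mm` (field centre in map coordinates).
#' @export
make_planar_field <- function(model, center_dose_Gy, size_mm = 30,
                              dpi = 300) {
  if (size_mm <= 0) stop("nonpositive extent")
  f <- planar_dose_function(model, center_dose_Gy)
  pitch <- 25.4 / dpi
  n <- floor(size_mm / pitch) + 1L
  coords <- (seq_len(n) - 1) * pitch
  cx <- coords[n] / 2
  dose <- outer(coords - cx, coords - cx,
                function(y, x) f(x, y))
  structure(list(dose = dose, dpi = dpi, center_mm = c(cx, cx)),
            class = "dose_map")
}

#' Film forward model: dose map to scan-image pair
#'
#' Simulates the physics the analysis inverts. Per pixel the true forward
#' response gives `dnetOD`, the post-irradiation signal is
#' `P = p_bg + (p0_mean - p_bg) * 10^(-dnetOD)`, then seeded additive
#' Gaussian noise (independent per pixel, same level for pre and post) is
#' added, and values are clipped and quantized to the scanner bit depth.
#'
#' @param dose_map A matrix of doses (Gy) or a [make_planar_field()]
#'   result.
#' @param spec A [synthetic_spec()].
#' @return A list with `pre` and `post` [scan_image()]s.
#' @export
film_forward_model <- function(dose_map, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  d <- if (inherits(dose_map, "dose_map")) dose_map$dose else dose_map
  stopifnot(is.matrix(d), all(d >= 0))
  delta <- netod_from_dose(spec$true_curve, d)
  p_clean <- spec$p_bg + (spec$p0_mean - spec$p_bg) * 10^(-delta)
  # quantized signal indistinguishable from background = unusable film
  if (any(round(p_clean) <= spec$p_bg)) stop("response saturated")
  set.seed(spec$seed)
  noise <- function() {
    if (spec$pixel_noise_sd == 0) 0
    else matrix(stats::rnorm(length(d), sd = spec$pixel_noise_sd), nrow(d))
  }
  quantize <- function(m) {
    m <- round(m)
    m[m < 0] <- 0
    top <- 2^spec$bit_depth - 1
    m[m > top] <- top
    storage.mode(m) <- "integer"
    m
  }
  pre_px <- quantize(matrix(spec$p0_mean, nrow(d), ncol(d)) + noise())
  post_px <- quantize(p_clean + noise())
  list(pre = scan_image(pre_px, dpi = spec$dpi, bit_depth = spec$bit_depth),
       post = scan_image(post_px, dpi = spec$dpi, bit_depth = spec$bit_depth))
}

#' Simulate a full planar scan pair for a plaque model
#'
#' Builds the model's planar dose field at the exposure implied by the
#' spec (dose rate x exposure time at the field centre), pushes it through
#' the film forward model, and optionally writes `pre.tif`, `post.tif`,
#' grid-point truth doses (`truth_dose.csv`) and the generator parameters
#' (`spec.json`) to a directory.
#'
#' @param spec A [synthetic_spec()].
#' @param center_dose_Gy Centre dose; default
#'   `dose_rate * exposure_minutes / 1000`.
#' @param size_mm Map side length.
#' @param out_dir Optional output directory.
#' @return A list with `pre`, `post`, `truth` (grid-point truth doses in
#'   canonical order), `grid`, and `center_mm`.
#' @export
simulate_scan_pair <- function(spec, center_dose_Gy = NULL, size_mm = 30,
                               out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(center_dose_Gy)) {
    center_dose_Gy <- delivered_dose(spec$dose_rate_mGy_per_min,
                                     spec$exposure_minutes)
  }
  field <- make_planar_field(spec$model, center_dose_Gy, size_mm = size_mm,
                             dpi = spec$dpi)
  pair <- film_forward_model(field, spec)
  grid <- build_reference_grid(spec$model)
  f <- planar_dose_function(spec$model, center_dose_Gy)
  truth <- f(grid$x_mm, grid$y_mm)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_scan(pair$pre, file.path(out_dir, "pre.tif"))
    write_scan(pair$post, file.path(out_dir, "post.tif"))
    utils::write.csv(
      cbind(as.data.frame(grid), truth_dose_Gy = truth),
      file.path(out_dir, "truth_dose.csv"), row.names = FALSE)
    meta <- unclass(spec)[setdiff(names(spec), c("model", "true_curve"))]
    meta$model <- spec$model$name
    meta$true_curve <- unclass(spec$true_curve)
    meta$center_dose_Gy <- center_dose_Gy
    jsonlite::write_json(meta, file.path(out_dir, "spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(pre = pair$pre, post = pair$post, truth = truth, grid = grid,
       center_mm = field$center_mm)
}

#' Simulate a film calibration series
#'
#' Generates one uniform-dose scan pair per schedule time (plus a 0 Gy
#' control film), measures a central 1-mm ROI on each, and returns the
#' calibration table of zero-normalized netOD versus delivered dose —
#' exactly the data [fit_inverse()] and [fit_forward()] consume. Each film
#' uses its own sub-seed derived from the spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @param times_min Irradiation times (min).
#' @param film_mm Side length of each uniform film patch.
#' @return A data frame with `time_min`, `dose_Gy`, `delta_netod`,
#'   `sd_netod`.
#' @export
simulate_calibration <- function(spec, times_min = c(2.5, 5, 10, 15, 20),
                                 film_mm = 4) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sched <- dose_schedule(times_min, spec$dose_rate_mGy_per_min)
  doses <- c(0, sched$dose_Gy)
  netods <- numeric(length(doses))
  sds <- numeric(length(doses))
  pitch <- 25.4 / spec$dpi
  npx <- floor(film_mm / pitch) + 1L
  c_mm <- (npx - 1) / 2 * pitch
  for (i in seq_along(doses)) {
    spec_i <- spec
    spec_i$seed <- spec$seed + i - 1L
    pair <- film_forward_model(matrix(doses[i], npx, npx), spec_i)
    roi <- roi_circle(c_mm, c_mm, 1)
    reading <- reading_from_rois(roi_stats(pair$pre, roi),
                                 roi_stats(pair$post, roi),
                                 p_bg = spec$p_bg)
    netods[i] <- net_od(reading)
    sds[i] <- sd_net_od(reading)
  }
  data.frame(time_min = c(0, sched$time_min), dose_Gy = doses,
             delta_netod = delta_net_od(netods, netods[1]),
             sd_netod = sds)
}
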