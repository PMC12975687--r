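#' Certified source data
#'
#' Certified reference dose rate of a Ru-106 applicator at its
#' certification date, with the isotope half-life used for decay
#' correction.
#'
#' @param certified_rate_mGy_per_min Certified dose rate (mGy/min, > 0).
#' @param cert_date Certification date (`Date` or parseable string);
#'   optional when elapsed times are supplied directly.
#' @param half_life_days Half-life in days; Ru-106 is 373.6.
#' @return An object of class `source_cert`.
#' @export
source_cert <- function(certified_rate_mGy_per_min, cert_date = NULL,
                        half_life_days = 373.6) {
  stopifnot(certified_rate_mGy_per_min > 0, half_life_days > 0)
  if (!is.null(cert_date)) cert_date <- as.Date(cert_date)
  structure(
    list(certified_rate_mGy_per_min = certified_rate_mGy_per_min,
         cert_date = cert_date, half_life_days = half_life_days),
    class = "source_cert"
  )
}

#' Decay-corrected dose rate
#'
#' Rescales the certified dose rate to the experiment date:
#' `rate * 2^(-elapsed_days / half_life_days)`. Either the elapsed time or
#' the measurement date (with a certified `cert_date`) may be given.
#' Negative elapsed times (pre-certification dates) are allowed with a
#' warning.
#'
#' @param cert A [source_cert()].
#' @param elapsed_days Days since certification.
#' @param on_date Measurement date; used with `cert$cert_date` when
#'   `elapsed_days` is missing.
#' @return Dose rate in mGy/min.
#' @export
decay_corrected_rate <- function(cert, elapsed_days = NULL, on_date = NULL) {
  stopifnot(inherits(cert, "source_cert"))
  if (is.null(elapsed_days)) {
    if (is.null(on_date) || is.null(cert$cert_date)) {
      stop("supply `elapsed_days`, or `on_date` with a certified date")
    }
    elapsed_days <- as.numeric(as.Date(on_date) - cert$cert_date)
  }
  if (any(elapsed_days < 0)) {
    warning("elapsed time is negative (date precedes certification)")
  }
  cert$certified_rate_mGy_per_min * 2^(-elapsed_days / cert$half_life_days)
}

#' Delivered dose
#'
#' Dose delivered by irradiating for a given time at a given dose rate:
#' `rate * minutes / 1000` Gy.
#'
#' @param rate_mGy_per_min Dose rate (mGy/min).
#' @param minutes Irradiation time (min).
#' @return Dose in Gy.
#' @export
delivered_dose <- function(rate_mGy_per_min, minutes) {
  stopifnot(all(rate_mGy_per_min >= 0), all(minutes >= 0))
  rate_mGy_per_min * minutes / 1000
}

#' Calibration dose schedule
#'
#' Builds the delivered-dose schedule from irradiation durations and a
#' decay-corrected dose rate. The reference protocol irradiates for 2.5,
#' 5, 10, 15 and 20 min at 120.1 mGy/min, spanning roughly 0.3-2.4 Gy.
#'
#' @param times_min Strictly increasing positive irradiation times (min).
#' @param rate_mGy_per_min Decay-corrected dose rate (mGy/min).
#' @return A data frame with `time_min` and `dose_Gy`.
#' @export
dose_schedule <- function(times_min = c(2.5, 5, 10, 15, 20),
                          rate_mGy_per_min = 120.1) {
  stopifnot(all(times_min > 0), !is.unsorted(times_min, strictly = TRUE),
            rate_mGy_per_min > 0)
  data.frame(time_min = times_min,
             dose_Gy = delivered_dose(rate_mGy_per_min, times_min))
}

#' Calibration curve object
#'
#' Fitted power-law response `y = a*x + b*x^n`. The `form` flag records the
#' direction: `"forward"` maps dose to delta-netOD, `"inverse"` maps
#' delta-netOD to dose. The two directions carry distinct parameter sets
#' that share symbol names only; they are never interchanged.
#'
#' @param form `"forward"` or `"inverse"`.
#' @param a,b,n Fit parameters (`n > 1`).
#' @param sd_a,sd_b Parameter standard deviations from the fit covariance
#'   (with `n` held at its estimate).
#' @param dose_range_Gy Validity window `[min, max]` in Gy.
#' @param r2 Coefficient of determination.
#' @param rss Residual sum of squares.
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(form = c("inverse", "forward"), a, b, n,
                              sd_a = 0, sd_b = 0,
                              dose_range_Gy = c(0, Inf), r2 = NA_real_,
                              rss = NA_real_) {
  form <- match.arg(form)
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(n), length(n) == 1L)
  if (n <= 1) stop("power-law exponent must satisfy n > 1")
  if (dose_range_Gy[1] < 0) stop("dose_range minimum must be >= 0")
  structure(
    list(form = form, a = a, b = b, n = n, sd_a = sd_a, sd_b = sd_b,
         dose_range_Gy = dose_range_Gy, r2 = r2, rss = rss),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> form=%s  a=%.6g (sd %.3g)  b=%.6g (sd %.3g)  n=%.6g\n",
    x$form, x$a, x$sd_a, x$b, x$sd_b, x$n))
  cat(sprintf("  dose range: %.3g - %.3g Gy   R^2 = %s\n",
              x$dose_range_Gy[1], x$dose_range_Gy[2],
              ifelse(is.na(x$r2), "NA", sprintf("%.6f", x$r2))))
  invisible(x)
}

# Least-squares fit of y = a*x + b*x^n by profiling the exponent: for fixed
# n the problem is linear in (a, b), so a coarse grid over n followed by
# golden-section refinement gives a deterministic global optimum without
# nonlinear-solver start-point sensitivity. Returns parameters plus the
# 2-parameter covariance of (a, b) evaluated with n held at its estimate.
fit_power_law <- function(x, y, weights = NULL,
                          n_bounds = c(1 + 1e-6, 5)) {
  stopifnot(length(x) == length(y))
  w <- if (is.null(weights)) rep(1, length(x)) else weights
  if (any(w <= 0)) stop("weights must be positive")
  sw <- sqrt(w)
  solve_for_n <- function(n) {
    X <- cbind(x, x^n) * sw
    fit <- stats::lm.fit(X, y * sw)
    list(n = n, coef = fit$coefficients, rss = sum(fit$residuals^2))
  }
  rss_of <- function(n) solve_for_n(n)$rss
  grid <- seq(n_bounds[1], n_bounds[2], by = 0.01)
  rss_grid <- vapply(grid, rss_of, numeric(1))
  i <- which.min(rss_grid)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(rss_of, c(lo, hi), tol = 1e-10)
  best <- solve_for_n(opt$minimum)
  # covariance of (a, b) with n fixed at its estimate
  X <- cbind(x, x^best$n) * sw
  dof <- length(x) - 3L  # a, b, n all estimated from the data
  sigma2 <- if (dof > 0) best$rss / dof else 0
  xtx_inv <- tryCatch(solve(crossprod(X)), error = function(e) {
    matrix(NA_real_, 2, 2)
  })
  cov_ab <- sigma2 * xtx_inv
  ybar <- sum(w * y) / sum(w)
  tss <- sum(w * (y - ybar)^2)
  list(a = unname(best$coef[1]), b = unname(best$coef[2]), n = best$n,
       sd_a = sqrt(cov_ab[1, 1]), sd_b = sqrt(cov_ab[2, 2]),
       rss = best$rss, r2 = 1 - best$rss / tss)
}

# Shared validation for the two fit directions.
check_calibration_points <- function(x, y, min_points = 4L) {
  if (length(x) == 0L || length(y) == 0L) stop("empty calibration input")
  stopifnot(length(x) == length(y))
  keep <- !duplicated(cbind(x, y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < min_points) {
    stop("calibration under-determined: need >= ", min_points,
         " distinct points, got ", length(x))
  }
  ord <- order(x)
  if (any(diff(y[ord]) < 0)) stop("calibration not monotone")
  list(x = x[ord], y = y[ord])
}

#' Fit the inverse calibration (delta-netOD to dose)
#'
#' Fits `D = a*dnetOD + b*dnetOD^n` by least squares. This direction is
#' fitted directly on the calibration points (not obtained by numerically
#' inverting the forward fit) and is the curve used to convert measured
#' film readings to absolute dose. An exact (0, 0) anchor is appended when
#' no near-zero point is present, reflecting the zero-dose normalization of
#' delta-netOD.
#'
#' @param delta_netods Normalized netOD values at the calibration points.
#' @param doses_Gy Delivered doses (Gy).
#' @param weights Optional least-squares weights (default unweighted).
#' @return A [calibration_curve()] with `form = "inverse"`; `dose_range_Gy`
#'   spans the positive calibration doses.
#' @export
fit_inverse <- function(delta_netods, doses_Gy, weights = NULL) {
  if (length(delta_netods) == 0L) stop("empty calibration input")
  if (length(unique(delta_netods)) < 4L) {
    stop("calibration under-determined: need >= 4 distinct points")
  }
  if (!any(abs(delta_netods) < 1e-9)) {
    delta_netods <- c(0, delta_netods)
    doses_Gy <- c(0, doses_Gy)
    if (!is.null(weights)) weights <- c(max(weights), weights)
  }
  pts <- check_calibration_points(delta_netods, doses_Gy)
  fit <- fit_power_law(pts$x, pts$y, weights = weights)
  calibration_curve("inverse", a = fit$a, b = fit$b, n = fit$n,
                    sd_a = fit$sd_a, sd_b = fit$sd_b,
                    dose_range_Gy = range(doses_Gy[doses_Gy > 0]),
                    r2 = fit$r2, rss = fit$rss)
}

#' Fit the forward dose-response (dose to delta-netOD)
#'
#' Fits `dnetOD = a*D + b*D^n`, the physical film-darkening response.
#' Mirrors [fit_inverse()] with the axes swapped.
#'
#' @param doses_Gy Delivered doses (Gy).
#' @param delta_netods Normalized netOD values.
#' @param weights Optional least-squares weights.
#' @return A [calibration_curve()] with `form = "forward"`.
#' @export
fit_forward <- function(doses_Gy, delta_netods, weights = NULL) {
  if (length(doses_Gy) == 0L) stop("empty calibration input")
  if (length(unique(doses_Gy)) < 4L) {
    stop("calibration under-determined: need >= 4 distinct points")
  }
  if (!any(abs(doses_Gy) < 1e-9)) {
    doses_Gy <- c(0, doses_Gy)
    delta_netods <- c(0, delta_netods)
    if (!is.null(weights)) weights <- c(max(weights), weights)
  }
  pts <- check_calibration_points(doses_Gy, delta_netods)
  fit <- fit_power_law(pts$x, pts$y, weights = weights)
  calibration_curve("forward", a = fit$a, b = fit$b, n = fit$n,
                    sd_a = fit$sd_a, sd_b = fit$sd_b,
                    dose_range_Gy = range(doses_Gy[doses_Gy > 0]),
                    r2 = fit$r2, rss = fit$rss)
}

#' Convert delta-netOD to dose
#'
#' Evaluates the inverse calibration `D = a*x + b*x^n`. Values implying a
#' dose outside the fitted range raise a warning (no uncertainty claims are
#' made outside the calibrated window; in particular nothing below the
#' smallest calibration dose is extrapolated). Small negative inputs within
#' `-1e-6` (noise around zero dose) are clamped to 0.
#'
#' @param curve A [calibration_curve()] with `form = "inverse"`.
#' @param delta_netod Normalized netOD (>= 0), vectorized.
#' @param warn_range Warn when the implied dose leaves `dose_range_Gy`.
#' @return Dose in Gy.
#' @export
dose_from_netod <- function(curve, delta_netod, warn_range = TRUE) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$form != "inverse") {
    stop("dose_from_netod needs an inverse-form curve")
  }
  if (any(delta_netod < -1e-6)) stop("negative delta-netOD")
  x <- pmax(delta_netod, 0)
  d <- curve$a * x + curve$b * x^curve$n
  if (warn_range && any(d > 0 & (d < curve$dose_range_Gy[1] |
                                 d > curve$dose_range_Gy[2]))) {
    warning(sprintf("dose outside calibrated range [%.3g, %.3g] Gy",
                    curve$dose_range_Gy[1], curve$dose_range_Gy[2]))
  }
  d
}

#' Evaluate the forward response (dose to delta-netOD)
#'
#' @param curve A [calibration_curve()] with `form = "forward"`.
#' @param dose_Gy Dose in Gy (>= 0), vectorized.
#' @return delta-netOD.
#' @export
netod_from_dose <- function(curve, dose_Gy) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$form != "forward") {
    stop("netod_from_dose needs a forward-form curve")
  }
  if (any(dose_Gy < 0)) stop("negative dose")
  curve$a * dose_Gy + curve$b * dose_Gy^curve$n
}

#' Numerically invert an inverse curve: delta-netOD at a given dose
#'
#' Solves `a*x + b*x^n = D` for `x` by bisection on the monotone fitted
#' response. Used when an uncertainty budget is requested at stated doses
#' rather than at measured netOD values.
#'
#' @param curve A [calibration_curve()] with `form = "inverse"`.
#' @param dose_Gy Target dose (Gy, >= 0), vectorized.
#' @return delta-netOD values.
#' @export
netod_for_dose <- function(curve, dose_Gy) {
  stopifnot(inherits(curve, "calibration_curve"), curve$form == "inverse")
  vapply(dose_Gy, function(d) {
    if (d < 0) stop("negative dose")
    if (d == 0) return(0)
    f <- function(x) curve$a * x + curve$b * x^curve$n - d
    hi <- 1
    while (f(hi) < 0) hi <- hi * 2
    stats::uniroot(f, c(0, hi), tol = 1e-12)$root
  }, numeric(1))
}

#' Serialize a calibration curve to JSON
#' @param curve A [calibration_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  jsonlite::write_json(unclass(curve), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration curve from JSON
#' @param path JSON path written by [write_curve()].
#' @return A [calibration_curve()].
#' @export
read_curve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_curve(form = obj$form, a = obj$a, b = obj$b, n = obj$n,
                    sd_a = obj$sd_a, sd_b = obj$sd_b,
                    dose_range_Gy = obj$dose_range_Gy, r2 = obj$r2,
                    rss = if (is.null(obj$rss)) NA_real_ else obj$rss)
}

#' Read a calibration table from CSV
#'
#' Expected columns: `time_min`, `delta_netod`, and optionally `sd_netod`.
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_calibration_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_min", "delta_netod") %in% names(df))) {
    stop("calibration table must have columns time_min and delta_netod")
  }
  if (is.null(df$sd_netod)) df$sd_netod <- NA_real_
  df
}
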