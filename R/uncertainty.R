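#' Fitting component of the dose uncertainty
#'
#' Percentage uncertainty in the converted dose attributable to the
#' calibration-fit parameter uncertainties:
#' `100 * sqrt(x^2*sd_a^2 + x^(2n)*sd_b^2) / D_fit`, with `x` the measured
#' delta-netOD and `D_fit` the fitted dose at `x`. The parameters `a` and
#' `b` are treated as uncorrelated and the exponent `n` as exact.
#'
#' @param curve A [calibration_curve()] with `form = "inverse"`.
#' @param delta_netod Measured delta-netOD (> 0), vectorized.
#' @return Percentage of fitted dose.
#' @export
sd_fit_percent <- function(curve, delta_netod) {
  stopifnot(inherits(curve, "calibration_curve"), curve$form == "inverse")
  if (any(delta_netod <= 0)) {
    stop("fitting uncertainty undefined at zero dose")
  }
  x <- delta_netod
  d_fit <- dose_from_netod(curve, x, warn_range = FALSE)
  100 * sqrt(x^2 * curve$sd_a^2 + x^(2 * curve$n) * curve$sd_b^2) / d_fit
}

#' Experimental component of the dose uncertainty
#'
#' Percentage uncertainty in the converted dose from the netOD measurement
#' noise, via the local slope of the inverse calibration:
#' `100 * (a + n*b*x^(n-1)) * sd_netod / D_fit`.
#'
#' @param curve A [calibration_curve()] with `form = "inverse"`.
#' @param delta_netod Measured delta-netOD (> 0), vectorized.
#' @param sd_netod Standard deviation of the netOD measurement (>= 0).
#' @return Percentage of fitted dose.
#' @export
sd_exp_percent <- function(curve, delta_netod, sd_netod) {
  stopifnot(inherits(curve, "calibration_curve"), curve$form == "inverse")
  if (any(delta_netod <= 0)) {
    stop("experimental uncertainty undefined at zero dose")
  }
  if (any(sd_netod < 0)) stop("sd_netod must be >= 0")
  x <- delta_netod
  d_fit <- dose_from_netod(curve, x, warn_range = FALSE)
  slope <- curve$a + curve$n * curve$b * x^(curve$n - 1)
  100 * slope * sd_netod / d_fit
}

#' Total dose uncertainty
#'
#' Quadrature sum of the experimental and fitting components:
#' `sqrt(sd_exp^2 + sd_fit^2)`, both in percent of fitted dose.
#'
#' @param sd_exp_pct Experimental component (%).
#' @param sd_fit_pct Fitting component (%).
#' @return Total uncertainty (%).
#' @export
sd_total_percent <- function(sd_exp_pct, sd_fit_pct) {
  if (any(sd_exp_pct < 0) || any(sd_fit_pct < 0)) {
    stop("uncertainty components must be >= 0")
  }
  sqrt(sd_exp_pct^2 + sd_fit_pct^2)
}

#' Expanded uncertainty
#'
#' Combined standard uncertainty multiplied by a coverage factor; `k = 2`
#' approximates a 95% confidence level and is the basis of the +/-11%
#' manufacturer certification bound this QA pipeline is measured against.
#'
#' @param sd_tot_pct Combined standard uncertainty (%).
#' @param k Coverage factor (> 0), default 2.
#' @return Expanded uncertainty (%).
#' @export
expanded_uncertainty <- function(sd_tot_pct, k = 2) {
  if (any(sd_tot_pct < 0)) stop("sd_tot_pct must be >= 0")
  if (k <= 0) stop("coverage factor must be > 0")
  k * sd_tot_pct
}

#' Dose-uncertainty budget at stated doses
#'
#' Evaluates the experimental, fitting, total and expanded (k-fold)
#' uncertainty percentages at a set of doses inside the calibrated range.
#' Doses outside the range are refused: no extrapolated uncertainty claims
#' are made below the smallest or above the largest calibration dose.
#'
#' @param curve A [calibration_curve()] with `form = "inverse"`.
#' @param doses_Gy Doses at which to evaluate the budget (Gy).
#' @param sd_netod Standard deviation of netOD; a scalar (applied to all
#'   doses) or a vector aligned with `doses_Gy`.
#' @param k Coverage factor for the expanded uncertainty.
#' @return A data frame of class `uncertainty_budget` with columns
#'   `dose_Gy`, `delta_netod`, `sd_exp_pct`, `sd_fit_pct`, `sd_tot_pct`,
#'   `expanded_pct` and attribute `k`.
#' @export
uncertainty_budget <- function(curve, doses_Gy, sd_netod, k = 2) {
  stopifnot(inherits(curve, "calibration_curve"), curve$form == "inverse")
  lo <- curve$dose_range_Gy[1]; hi <- curve$dose_range_Gy[2]
  if (any(doses_Gy < lo - 1e-9 | doses_Gy > hi + 1e-9)) {
    stop(sprintf(
      "budget undefined outside the calibrated range [%.3g, %.3g] Gy; no extrapolation",
      lo, hi))
  }
  sd_netod <- rep_len(sd_netod, length(doses_Gy))
  x <- netod_for_dose(curve, doses_Gy)
  fit_pct <- sd_fit_percent(curve, x)
  exp_pct <- sd_exp_percent(curve, x, sd_netod)
  tot_pct <- sd_total_percent(exp_pct, fit_pct)
  out <- data.frame(dose_Gy = doses_Gy, delta_netod = x,
                    sd_exp_pct = exp_pct, sd_fit_pct = fit_pct,
                    sd_tot_pct = tot_pct,
                    expanded_pct = expanded_uncertainty(tot_pct, k))
  attr(out, "k") <- k
  class(out) <- c("uncertainty_budget", "data.frame")
  out
}

#' Write an uncertainty budget to JSON
#' @param budget An [uncertainty_budget()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_budget <- function(budget, path) {
  stopifnot(inherits(budget, "uncertainty_budget"))
  jsonlite::write_json(
    list(k = attr(budget, "k"), budget = as.data.frame(budget)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
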