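#' Central-axis depth-dose profile
#'
#' Dose samples along the plaque central axis. Depths must be strictly
#' increasing. An optional scalar depth offset (detector air gap plus
#' sensitive-volume offset) can be applied before fitting.
#'
#' @param depths_mm Strictly increasing depths (mm).
#' @param doses Dose values (raw or normalized).
#' @param normalization_depth_mm Reference depth for normalization
#'   (default 2 mm).
#' @param depth_offset_mm Scalar added to all depths before analysis
#'   (default 0: depths assumed already corrected).
#' @return An object of class `depth_dose_profile`.
#' @export
depth_dose_profile <- function(depths_mm, doses, normalization_depth_mm = 2,
                               depth_offset_mm = 0) {
  stopifnot(length(depths_mm) == length(doses), all(is.finite(depths_mm)),
            all(is.finite(doses)))
  if (is.unsorted(depths_mm, strictly = TRUE)) {
    stop("depths must be strictly increasing")
  }
  structure(
    list(depths_mm = depths_mm + depth_offset_mm, doses = doses,
         normalization_depth_mm = normalization_depth_mm),
    class = "depth_dose_profile"
  )
}

#' Quartic fit of a depth-dose profile
#'
#' Least-squares degree-4 polynomial of dose versus depth, matching the
#' certificate convention for the central-axis profile. With exactly 5
#' distinct depths the fit interpolates the points exactly.
#'
#' @param profile A [depth_dose_profile()], or a numeric vector of depths
#'   when `doses` is given.
#' @param doses Dose values (when `profile` is a depth vector).
#' @param normalization_depth_mm Reference depth carried into the fit.
#' @return An object of class `quartic_fit` with coefficients `c0..c4`
#'   (`$coef`), residual RMS (`$rms`), the fitted depth span
#'   (`$depth_range_mm`) and the normalization depth.
#' @export
fit_quartic <- function(profile, doses = NULL, normalization_depth_mm = 2) {
  if (!inherits(profile, "depth_dose_profile")) {
    profile <- depth_dose_profile(profile, doses,
                                  normalization_depth_mm = normalization_depth_mm)
  }
  d <- profile$depths_mm
  y <- profile$doses
  if (anyDuplicated(d)) stop("duplicate depths")
  if (length(d) < 5L) stop("quartic fit needs >= 5 distinct depths")
  X <- outer(d, 0:4, `^`)
  fit <- stats::lm.fit(X, y)
  structure(
    list(coef = unname(fit$coefficients),
         rms = sqrt(mean(fit$residuals^2)),
         depth_range_mm = range(d),
         normalization_depth_mm = profile$normalization_depth_mm),
    class = "quartic_fit"
  )
}

#' Evaluate a quartic fit (unnormalized)
#'
#' @param fit A `quartic_fit` object from [fit_quartic()].
#' @param depths_mm Depths at which to evaluate (mm).
#' @return Polynomial values.
#' @export
evaluate_quartic <- function(fit, depths_mm) {
  stopifnot(inherits(fit, "quartic_fit"))
  drop(outer(depths_mm, 0:4, `^`) %*% fit$coef)
}

#' Normalized fitted doses at certified depths
#'
#' Evaluates the quartic fit at the certificate depths and normalizes by
#' the fitted value at the reference depth (2 mm), so the value at 2 mm is
#' exactly 1. Depths may extend up to 1 mm beyond the fitted span (the
#' certificate's shallowest point, 0.83 mm, lies just below the shallowest
#' measurable detector depth); anything further is refused.
#'
#' @param fit A `quartic_fit` object from [fit_quartic()].
#' @param depths_mm Certified depths (mm).
#' @param normalize Divide by the fitted value at the normalization depth.
#' @return Normalized doses at `depths_mm`.
#' @export
evaluate_at_certified <- function(fit, depths_mm, normalize = TRUE) {
  stopifnot(inherits(fit, "quartic_fit"))
  lo <- fit$depth_range_mm[1] - 1
  hi <- fit$depth_range_mm[2] + 1
  if (any(depths_mm < lo | depths_mm > hi)) {
    stop(sprintf("depth outside fitted span [%.2f, %.2f] mm (+/- 1 mm)",
                 fit$depth_range_mm[1], fit$depth_range_mm[2]))
  }
  v <- evaluate_quartic(fit, depths_mm)
  if (normalize) v <- v / evaluate_quartic(fit, fit$normalization_depth_mm)
  v
}

#' Compare measured and reference normalized depth-dose profiles
#'
#' Per-depth differences are in percentage points of normalized dose,
#' `(measured - reference) * 100` (the profiles are normalized to 1 at
#' 2 mm, so a difference of 1 means 0.01 in normalized dose). The summary
#' reports the mean and population standard deviation (divisor N) of the
#' absolute differences, plus the signed minimum and maximum.
#'
#' @param measured Normalized measured doses at the certified depths.
#' @param reference Normalized reference doses, same depths and order.
#' @param relative Use relative percent `100*(m - r)/r` instead of
#'   percentage points (sensitivity checks only).
#' @return An object of class `profile_comparison` with
#'   `per_depth_diff_pp`, `mean_abs_pp`, `sd_abs_pp`, `min_pp`, `max_pp`.
#' @export
compare_profiles <- function(measured, reference, relative = FALSE) {
  if (length(measured) != length(reference)) {
    stop("measured and reference profiles differ in length")
  }
  diff_pp <- if (relative) {
    100 * (measured - reference) / reference
  } else {
    (measured - reference) * 100
  }
  a <- abs(diff_pp)
  structure(
    list(per_depth_diff_pp = diff_pp,
         mean_abs_pp = mean(a),
         sd_abs_pp = sqrt(mean((a - mean(a))^2)),
         min_pp = min(diff_pp),
         max_pp = max(diff_pp)),
    class = "profile_comparison"
  )
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf(
    "<profile_comparison> mean |diff| = %.2f pp (pop. SD %.2f), range [%.2f, %.2f] pp over %d depths\n",
    x$mean_abs_pp, x$sd_abs_pp, x$min_pp, x$max_pp,
    length(x$per_depth_diff_pp)))
  invisible(x)
}

#' Dual-depth central-axis dose ratio
#'
#' The dose at 3 mm depth expressed as a percentage of the dose at 1 mm:
#' `100 * dose_3mm / dose_1mm`. This steepness index of the beta depth
#' dose is the headline certificate check for Ru-106 applicators (values
#' run in the mid-50s of percent).
#'
#' @param dose_1mm Dose at 1 mm depth (Gy, > 0).
#' @param dose_3mm Dose at 3 mm depth (Gy, > 0).
#' @return Ratio in percent.
#' @export
dual_depth_ratio <- function(dose_1mm, dose_3mm) {
  if (any(dose_1mm <= 0) || any(dose_3mm <= 0)) {
    stop("doses must be positive")
  }
  100 * dose_3mm / dose_1mm
}

#' Bundled central-axis microdiamond comparison table
#'
#' The published CCA central-axis comparison: certified reference and
#' microdiamond-measured normalized doses at the 11 certified depths
#' (0.83-10.00 mm, normalized at 2 mm) and the per-depth differences in
#' percentage points as computed on the unrounded measurements.
#'
#' @return A data frame with columns `depth_mm`, `reference_norm`,
#'   `measured_norm`, `diff_pp`.
#' @export
cax_reference_table <- function() {
  path <- system.file("extdata", "cax_cca_microdiamond.csv",
                      package = "plaquefilm")
  utils::read.csv(path)
}

#' Read a depth-dose CSV
#'
#' Expected columns: `depth_mm`, `dose`.
#'
#' @param path CSV file path.
#' @param normalization_depth_mm Reference depth.
#' @param depth_offset_mm Scalar depth correction.
#' @return A [depth_dose_profile()].
#' @export
read_depth_dose <- function(path, normalization_depth_mm = 2,
                            depth_offset_mm = 0) {
  df <- utils::read.csv(path)
  if (!all(c("depth_mm", "dose") %in% names(df))) {
    stop("depth-dose table must have columns depth_mm and dose")
  }
  depth_dose_profile(df$depth_mm, df$dose,
                     normalization_depth_mm = normalization_depth_mm,
                     depth_offset_mm = depth_offset_mm)
}
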