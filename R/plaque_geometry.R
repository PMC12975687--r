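#' Plaque model definitions
#'
#' Loads the geometry and certified reference data of a Ru-106 eye-plaque
#' model. Built-in definitions cover the three common applicator designs:
#' `CCA` (fully circular, 15.3 mm active diameter), `COB` (optic-nerve
#' notch, 19.8 mm) and `CIB` (iris notch, 20.2 mm). Each definition
#' carries:
#'
#' * the certified central-axis depth-dose table (11 depths, normalized to
#'   1.0 at 2 mm) — the CCA table is the published certificate profile;
#'   the COB and CIB tables are synthetic stand-ins (the certificates are
#'   not public) constrained to reproduce the certified dual-depth ratios,
#' * the certified 1 mm / 3 mm dual-depth dose ratio,
#' * a 33-point planar reference-dose grid for a standard 15-min QA
#'   exposure (synthetic stand-in values for all models),
#' * the analytic planar-field parameters used by the synthetic scan
#'   generator (radial fall-off plus a notch sector for COB/CIB).
#'
#' @param name `"CCA"`, `"COB"`, `"CIB"`, or a path to a JSON file in the
#'   same schema.
#' @return An object of class `plaque_model`.
#' @export
plaque_model <- function(name) {
  path <- if (file.exists(name)) {
    name
  } else {
    p <- system.file("extdata", paste0("plaque_", toupper(name), ".json"),
                     package = "plaquefilm")
    if (p == "") stop("unknown plaque model '", name, "'")
    p
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$certified_cax <- as.data.frame(obj$certified_cax)
  model <- structure(obj, class = "plaque_model")
  validate_plaque_model(model)
  model
}

validate_plaque_model <- function(model) {
  need <- c("name", "diameter_mm", "notch", "point_spacing_mm",
            "film_radius_mm", "certified_cax", "certified_ratio_pct",
            "certified_planar", "field")
  miss <- setdiff(need, names(model))
  if (length(miss)) stop("plaque model missing fields: ",
                         paste(miss, collapse = ", "))
  if (!model$notch %in% c("none", "optic", "iris")) {
    stop("notch must be one of none/optic/iris")
  }
  if (model$point_spacing_mm < 2.55 - 1e-9 ||
      model$point_spacing_mm > 3.37 + 1e-9) {
    stop("point spacing outside the supported 2.55-3.37 mm window")
  }
  cax <- model$certified_cax
  if (!all(c("depth_mm", "normalized_dose") %in% names(cax))) {
    stop("certified_cax needs columns depth_mm and normalized_dose")
  }
  at2 <- cax$normalized_dose[abs(cax$depth_mm - 2) < 1e-9]
  if (length(at2) != 1L || abs(at2 - 1) > 1e-6) {
    stop("certified_cax must be normalized to 1.0 at 2 mm depth")
  }
  invisible(model)
}

#' @export
print.plaque_model <- function(x, ...) {
  cat(sprintf(
    "<plaque_model> %s: %.1f mm active diameter, notch=%s, spacing %.2f mm\n",
    x$name, x$diameter_mm, x$notch, x$point_spacing_mm))
  cat(sprintf("  certified 3mm/1mm ratio: %.1f%%; %d certified CAX depths\n",
              x$certified_ratio_pct, nrow(x$certified_cax)))
  invisible(x)
}

#' Build the 33-point certified reference grid
#'
#' Reference measurement points are laid out along the x, y and two
#' diagonal (d1, d2) axes around the film centre: one centre point plus 8
#' points per axis at signed multiples (1..4) of the per-model point
#' spacing, 33 points in all. Nested radial regions are assigned by
#' per-axis index: `R1` covers the centre and indices `|i| <= 2`
#' (17 points), `R2` adds `|i| = 3` (25 cumulative), `R3` adds `|i| = 4`
#' (33 cumulative). Positions are in mm from the centre along the
#' flattened-film (arc-length) coordinate.
#'
#' Canonical row order — centre first, then axes x, y, d1, d2 each with
#' indices -4..-1, 1..4 — is shared by the certified planar reference
#' vectors and all planar-analysis functions.
#'
#' @param model A [plaque_model()].
#' @return A data frame of class `reference_grid` with columns `axis`,
#'   `index`, `x_mm`, `y_mm`, `region`, and attribute `spacing_mm`.
#' @export
build_reference_grid <- function(model) {
  stopifnot(inherits(model, "plaque_model"))
  s <- model$point_spacing_mm
  if (4 * s > model$film_radius_mm) stop("grid exceeds film")
  dirs <- list(x = c(1, 0), y = c(0, 1),
               d1 = c(1, 1) / sqrt(2), d2 = c(1, -1) / sqrt(2))
  idx <- c(-4:-1, 1:4)
  rows <- list(data.frame(axis = "center", index = 0L, x_mm = 0, y_mm = 0))
  for (ax in names(dirs)) {
    u <- dirs[[ax]]
    rows[[length(rows) + 1L]] <- data.frame(
      axis = ax, index = idx, x_mm = idx * s * u[1], y_mm = idx * s * u[2])
  }
  grid <- do.call(rbind, rows)
  grid$region <- ifelse(abs(grid$index) <= 2, "R1",
                        ifelse(abs(grid$index) == 3, "R2", "R3"))
  attr(grid, "spacing_mm") <- s
  class(grid) <- c("reference_grid", "data.frame")
  grid
}

#' Indices of the cumulative region point sets
#'
#' The radial regions are nested: `R1` is the innermost 17-point set, `R2`
#' the 25-point set including R1, `R3` all 33 points.
#'
#' @param grid A [build_reference_grid()] result.
#' @param region `"R1"`, `"R2"` or `"R3"`.
#' @return Integer row indices into `grid`.
#' @export
region_point_set <- function(grid, region = c("R1", "R2", "R3")) {
  region <- match.arg(region)
  max_idx <- c(R1 = 2L, R2 = 3L, R3 = 4L)[[region]]
  which(abs(grid$index) <= max_idx)
}

#' Low-dose exclusion filter
#'
#' Keeps the points receiving at least 5% of the maximum dose; points
#' receiving less are excluded from comparison (peripheral points beyond
#' the active area and under notches fall below this threshold). The
#' boundary is inclusive — the rule excludes strictly-less-than-threshold
#' points — and the maximum-dose point always survives.
#'
#' @param doses Per-point dose values (>= 1 point, not all zero).
#' @param threshold Fraction of the maximum dose; default 0.05.
#' @return Sorted integer indices of the kept points.
#' @export
low_dose_filter <- function(doses, threshold = 0.05) {
  if (length(doses) < 1L) stop("need at least one point")
  if (!all(is.finite(doses))) stop("doses must be finite")
  m <- max(doses)
  if (m <= 0) stop("no signal: all doses are <= 0")
  which(doses >= threshold * m)
}
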