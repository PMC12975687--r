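#' Measure planar doses at the reference grid points
#'
#' Runs the full densitometry chain at each grid point: 1-mm circular ROI
#' statistics on the red channels of the pre- and post-irradiation scans,
#' netOD, zero-dose normalization, and conversion to dose through the
#' inverse calibration. Grid coordinates are relative to the plaque
#' centre; `center_mm` places that centre in image coordinates (default:
#' the image midpoint). Negative delta-netOD from noise around zero dose
#' is clamped to 0. Doses whose value falls outside the calibrated range
#' are returned but flagged (`in_range = FALSE`).
#'
#' @param post Post-irradiation [scan_image()] (RGB or single-channel).
#' @param pre Pre-irradiation [scan_image()] of the same film.
#' @param grid A [build_reference_grid()] result.
#' @param curve Inverse [calibration_curve()].
#' @param zero_netod netOD of the unirradiated control film (default 0).
#' @param p_bg Background pixel value.
#' @param center_mm Length-2 vector `(x, y)` of the plaque centre in image
#'   mm coordinates.
#' @param roi_diameter_mm ROI diameter; the protocol uses 1 mm.
#' @param se Use standard-error semantics for ROI SDs (see
#'   [reading_from_rois()]).
#' @return A data frame: the grid columns plus `p0`, `p`, `delta_netod`,
#'   `sd_netod`, `dose_Gy`, `in_range`.
#' @export
measure_planar <- function(post, pre, grid, curve, zero_netod = 0,
                           p_bg = 0, center_mm = NULL,
                           roi_diameter_mm = 1, se = FALSE) {
  stopifnot(inherits(grid, "reference_grid"),
            inherits(curve, "calibration_curve"))
  post <- extract_red_channel(post)
  pre <- extract_red_channel(pre)
  if (is.null(center_mm)) {
    pitch <- 25.4 / post$dpi
    center_mm <- c((ncol(post$pixels) - 1) / 2,
                   (nrow(post$pixels) - 1) / 2) * pitch
  }
  out <- as.data.frame(grid)
  n <- nrow(out)
  out$p0 <- out$p <- out$delta_netod <- out$sd_netod <- out$dose_Gy <-
    rep(NA_real_, n)
  for (i in seq_len(n)) {
    roi <- roi_circle(center_mm[1] + out$x_mm[i],
                      center_mm[2] + out$y_mm[i],
                      roi_diameter_mm)
    st_pre <- roi_stats(pre, roi)
    st_post <- roi_stats(post, roi)
    reading <- reading_from_rois(st_pre, st_post, p_bg = p_bg, se = se)
    dn <- max(0, delta_net_od(net_od(reading), zero_netod))
    out$p0[i] <- st_pre$mean_pv
    out$p[i] <- st_post$mean_pv
    out$delta_netod[i] <- dn
    out$sd_netod[i] <- sd_net_od(reading)
    out$dose_Gy[i] <- dose_from_netod(curve, dn, warn_range = FALSE)
  }
  out$in_range <- out$dose_Gy >= curve$dose_range_Gy[1] &
    out$dose_Gy <= curve$dose_range_Gy[2]
  out
}

#' Compare measured planar doses with certified reference doses
#'
#' Applies the 5%-of-maximum exclusion filter to the *reference* doses (so
#' the excluded set does not depend on measurement noise), computes the
#' per-point relative difference `100 * (measured - reference)/reference`
#' for the surviving points, and summarizes the absolute differences by
#' cumulative region: R1 (innermost 17 points), R2 (25), R3 (all 33),
#' intersected with the kept set. Summary SDs are population SDs.
#'
#' @param measured 33 measured doses in canonical grid order (a numeric
#'   vector or a [measure_planar()] result).
#' @param model A [plaque_model()] supplying `certified_planar`.
#' @param grid The matching [build_reference_grid()] result.
#' @param reference Optional explicit reference doses (overrides the
#'   model's `certified_planar`).
#' @return An object of class `planar_comparison` with `per_point` (data
#'   frame), `region_summary` (region, n, mean_pct, sd_pct) and
#'   `excluded_points` (grid row indices removed by the filter).
#' @export
compare_planar <- function(measured, model, grid, reference = NULL) {
  stopifnot(inherits(grid, "reference_grid"))
  if (is.data.frame(measured)) measured <- measured$dose_Gy
  if (is.null(reference)) {
    stopifnot(inherits(model, "plaque_model"))
    reference <- model$certified_planar
  }
  if (length(measured) != nrow(grid) || length(reference) != nrow(grid)) {
    stop("measured/reference must align with the grid (one dose per point)")
  }
  kept <- low_dose_filter(reference)
  per_point <- data.frame(
    point = seq_len(nrow(grid)),
    axis = grid$axis, index = grid$index, region = grid$region,
    measured_Gy = measured, reference_Gy = reference,
    kept = seq_len(nrow(grid)) %in% kept,
    diff_pct = NA_real_
  )
  per_point$diff_pct[kept] <-
    100 * (measured[kept] - reference[kept]) / reference[kept]
  summarize_region <- function(reg) {
    pts <- intersect(region_point_set(grid, reg), kept)
    a <- abs(per_point$diff_pct[pts])
    data.frame(region = reg, n = length(pts),
               mean_pct = if (length(a)) mean(a) else NA_real_,
               sd_pct = if (length(a)) sqrt(mean((a - mean(a))^2)) else NA_real_)
  }
  structure(
    list(per_point = per_point,
         region_summary = do.call(rbind, lapply(c("R1", "R2", "R3"),
                                                summarize_region)),
         excluded_points = setdiff(seq_len(nrow(grid)), kept)),
    class = "planar_comparison"
  )
}

#' @export
print.planar_comparison <- function(x, ...) {
  cat("<planar_comparison>\n")
  print(x$region_summary, row.names = FALSE)
  if (length(x$excluded_points)) {
    cat("  excluded by 5% filter:", length(x$excluded_points), "point(s)\n")
  }
  invisible(x)
}

#' Extract a dose profile along one grid axis
#'
#' Orders the centre point and the 8 points of one axis by signed
#' position, in mm from the centre.
#'
#' @param measured 33 doses in canonical grid order (vector or
#'   [measure_planar()] result).
#' @param grid A [build_reference_grid()] result.
#' @param axis `"x"`, `"y"`, `"d1"` or `"d2"`.
#' @return A data frame with `position_mm` and `dose`, 9 rows.
#' @export
extract_axis_profile <- function(measured, grid, axis) {
  stopifnot(inherits(grid, "reference_grid"))
  if (is.data.frame(measured)) measured <- measured$dose_Gy
  if (!axis %in% c("x", "y", "d1", "d2")) stop("unknown axis '", axis, "'")
  sel <- grid$axis %in% c("center", axis)
  pos <- grid$index[sel] * attr(grid, "spacing_mm")
  ord <- order(pos)
  data.frame(position_mm = pos[ord], dose = measured[sel][ord])
}

#' Write a planar comparison to CSV files
#'
#' @param cmp A [compare_planar()] result.
#' @param summary_path CSV path for the region summary.
#' @param points_path Optional CSV path for the per-point table.
#' @return `summary_path`, invisibly.
#' @export
write_planar_comparison <- function(cmp, summary_path, points_path = NULL) {
  stopifnot(inherits(cmp, "planar_comparison"))
  utils::write.csv(cmp$region_summary, summary_path, row.names = FALSE)
  if (!is.null(points_path)) {
    utils::write.csv(cmp$per_point, points_path, row.names = FALSE)
  }
  invisible(summary_path)
}
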