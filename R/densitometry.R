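#' Film reading: paired pre/post pixel values
#'
#' Holds the mean red-channel pixel values of one ROI before (`p0`) and
#' after (`p`) irradiation, the scan-session background level `p_bg`, and
#' the pixel-value standard deviations feeding the netOD uncertainty
#' propagation. Both signals must sit above background.
#'
#' @param p0 Pre-irradiation mean pixel value.
#' @param p Post-irradiation mean pixel value.
#' @param p_bg Background pixel value (one scalar per scan session; the
#'   default 0 corresponds to no background reading).
#' @param sd_p0,sd_p Standard deviations of `p0` and `p` (>= 0).
#' @return An object of class `film_reading`.
#' @export
film_reading <- function(p0, p, p_bg = 0, sd_p0 = 0, sd_p = 0) {
  stopifnot(is.numeric(p0), is.numeric(p), is.numeric(p_bg))
  if (any(sd_p0 < 0) || any(sd_p < 0)) stop("pixel-value SDs must be >= 0")
  if (any(p0 <= p_bg) || any(p <= p_bg)) {
    stop("background exceeds signal: need p0 > p_bg and p > p_bg")
  }
  structure(
    list(p0 = p0, p = p, p_bg = p_bg, sd_p0 = sd_p0, sd_p = sd_p),
    class = "film_reading"
  )
}

#' Build a film reading from ROI statistics
#'
#' Pairs the ROI statistics of a pre-scan and a post-scan into a
#' [film_reading()]. By default the ROI pixel-value SDs are used directly,
#' matching the netOD propagation formula written in terms of pixel-value
#' SDs; with `se = TRUE` they are divided by `sqrt(n_pixels)` to give
#' standard errors of the ROI means.
#'
#' @param pre_stat,post_stat `roi_stat` objects from [roi_stats()].
#' @param p_bg Background pixel value.
#' @param se Use standard-error semantics for the SDs.
#' @return A [film_reading()].
#' @export
reading_from_rois <- function(pre_stat, post_stat, p_bg = 0, se = FALSE) {
  stopifnot(inherits(pre_stat, "roi_stat"), inherits(post_stat, "roi_stat"))
  s0 <- pre_stat$sd_pv
  s1 <- post_stat$sd_pv
  if (se) {
    s0 <- s0 / sqrt(pre_stat$n_pixels)
    s1 <- s1 / sqrt(post_stat$n_pixels)
  }
  film_reading(p0 = pre_stat$mean_pv, p = post_stat$mean_pv, p_bg = p_bg,
               sd_p0 = s0, sd_p = s1)
}

#' Net optical density of a film reading
#'
#' `netOD = log10((P0 - Pbg) / (P - Pbg))`: the log-ratio of the
#' background-corrected pre- and post-irradiation signals. Oriented so that
#' netOD increases with dose (the film darkens, so `P < P0`), consistent
#' with the Devic radiochromic-film formalism and a monotone-increasing
#' calibration. `orientation = "p_over_p0"` flips the ratio for forensic
#' comparison with analyses using the opposite sign convention.
#'
#' @param reading A [film_reading()].
#' @param orientation Ratio orientation; default puts the pre-scan signal
#'   in the numerator.
#' @return Net optical density (dimensionless).
#' @export
net_od <- function(reading, orientation = c("p0_over_p", "p_over_p0")) {
  stopifnot(inherits(reading, "film_reading"))
  orientation <- match.arg(orientation)
  num <- reading$p0 - reading$p_bg
  den <- reading$p - reading$p_bg
  v <- log10(num / den)
  if (orientation == "p_over_p0") -v else v
}

#' Zero-dose normalized netOD
#'
#' Re-zeroes a film's netOD against an unirradiated control film scanned in
#' the same session, anchoring the dose-response at (0 Gy, 0).
#'
#' @param net_od_irr netOD of the irradiated film.
#' @param net_od_zero netOD of the 0 Gy control film.
#' @return `net_od_irr - net_od_zero`.
#' @export
delta_net_od <- function(net_od_irr, net_od_zero) {
  if (!all(is.finite(net_od_irr)) || !all(is.finite(net_od_zero))) {
    stop("netOD values must be finite")
  }
  net_od_irr - net_od_zero
}

#' Propagated standard deviation of netOD
#'
#' First-order propagation of the pixel-value SDs through the log-ratio:
#' `SD_netOD = (1/ln 10) * sqrt(SD_P0^2/(P0-Pbg)^2 + SD_P^2/(P-Pbg)^2)`.
#' `Pbg` is treated as exact.
#'
#' @param reading A [film_reading()].
#' @return Standard deviation of netOD (dimensionless, >= 0).
#' @export
sd_net_od <- function(reading) {
  stopifnot(inherits(reading, "film_reading"))
  num <- reading$p0 - reading$p_bg
  den <- reading$p - reading$p_bg
  sqrt(reading$sd_p0^2 / num^2 + reading$sd_p^2 / den^2) / log(10)
}

#' Read a film-readings table from CSV
#'
#' Expected columns: `label`, `p0`, `sd_p0`, `p`, `sd_p`, `p_bg`. Missing
#' SD columns default to 0, a missing `p_bg` column to 0.
#'
#' @param path CSV file path.
#' @return A data frame with one [film_reading()] per row in
#'   `$reading`, plus the original columns.
#' @export
read_readings_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("p0", "p") %in% names(df))) {
    stop("readings table must have columns p0 and p")
  }
  for (col in c("sd_p0", "sd_p", "p_bg")) {
    if (is.null(df[[col]])) df[[col]] <- 0
  }
  if (is.null(df$label)) df$label <- seq_len(nrow(df))
  df$reading <- lapply(seq_len(nrow(df)), function(i) {
    film_reading(df$p0[i], df$p[i], df$p_bg[i], df$sd_p0[i], df$sd_p[i])
  })
  df
}
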