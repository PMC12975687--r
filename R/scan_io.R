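#' Scanned film image
#'
#' Container for a flatbed scan of a radiochromic film. Pixels are stored as
#' an integer matrix (single channel, rows = y, columns = x) or a
#' rows x cols x channels array (RGB). Physical coordinates follow the scan
#' raster: the origin sits at the centre of the top-left pixel, x runs
#' rightward, y downward, and `mm = pixel_index * 25.4 / dpi`.
#'
#' @param pixels Numeric matrix or 3-d array of raw pixel values.
#' @param dpi Scan resolution in dots per inch (> 0).
#' @param bit_depth Scanner bit depth; 8 to 16.
#' @return An object of class `scan_image` with fields `pixels`, `dpi`,
#'   `bit_depth` and `channels`.
#' @export
scan_image <- function(pixels, dpi, bit_depth = 16L) {
  if (!is.numeric(pixels) || is.null(dim(pixels)) ||
      !(length(dim(pixels)) %in% c(2L, 3L))) {
    stop("`pixels` must be a numeric matrix or 3-d array")
  }
  bit_depth <- as.integer(bit_depth)
  if (is.na(bit_depth) || bit_depth < 8L || bit_depth > 16L) {
    stop("unsupported bit depth: ", bit_depth, " (must be 8..16)")
  }
  if (!is.numeric(dpi) || length(dpi) != 1L || !is.finite(dpi) || dpi <= 0) {
    stop("`dpi` must be a single positive number")
  }
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 2^bit_depth - 1) {
    stop("pixel values outside [0, 2^bit_depth - 1]")
  }
  channels <- if (length(dim(pixels)) == 2L) 1L else dim(pixels)[3L]
  structure(
    list(pixels = pixels, dpi = as.numeric(dpi), bit_depth = bit_depth,
         channels = channels),
    class = "scan_image"
  )
}

#' @export
print.scan_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<scan_image> %d x %d px, %d channel(s), %d-bit, %g dpi\n",
              d[1], d[2], x$channels, x$bit_depth, x$dpi))
  invisible(x)
}

#' Read a scanned film TIFF
#'
#' Reads an 8- or 16-bit grayscale or RGB TIFF as raw integer pixel values.
#' The resolution is taken from the TIFF resolution tags when present and
#' expressed in inches; otherwise `dpi` must be supplied (scanners in this
#' workflow run at 300 dpi reflection mode, and synthetic scans carry their
#' dpi in a sidecar spec).
#'
#' @param path Path to a TIFF file.
#' @param dpi Optional resolution override in dots per inch.
#' @return A [scan_image()].
#' @export
read_scan <- function(path, dpi = NULL) {
  if (!file.exists(path)) stop("unreadable scan: no such file '", path, "'")
  raw <- tryCatch(
    tiff::readTIFF(path, as.is = TRUE, info = TRUE),
    error = function(e) stop("unreadable scan '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  bits <- attr(raw, "bits.per.sample")
  if (is.null(bits)) bits <- 8L
  if (bits < 8L || bits > 16L) {
    stop("unsupported bit depth in '", path, "': ", bits)
  }
  file_dpi <- attr(raw, "x.resolution")
  unit <- attr(raw, "resolution.unit")
  if (!is.null(file_dpi) && !is.null(unit) && !identical(unit, "inch")) {
    file_dpi <- NULL  # only inch-based tags map directly to dpi
  }
  use_dpi <- if (!is.null(dpi)) dpi else file_dpi
  if (is.null(use_dpi)) {
    stop("scan '", path, "' carries no dpi metadata; supply `dpi`")
  }
  pixels <- unclass(raw)
  attributes(pixels) <- list(dim = dim(raw))
  scan_image(pixels, dpi = use_dpi, bit_depth = bits)
}

#' Write a scan image to TIFF
#'
#' Uncompressed output so synthetic fixtures round-trip bit-identically.
#'
#' @param img A [scan_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(img, path) {
  stopifnot(inherits(img, "scan_image"))
  scale <- 2^img$bit_depth - 1
  tiff::writeTIFF(img$pixels / scale, path,
                  bits.per.sample = img$bit_depth, compression = "none")
  invisible(path)
}

#' Extract the red channel
#'
#' Film densitometry in this pipeline uses only the red channel of RGB
#' scans, where the dye's dose sensitivity is highest. Single-channel
#' images pass through unchanged.
#'
#' @param img A [scan_image()] with 1 or 3 channels.
#' @return A single-channel [scan_image()].
#' @export
extract_red_channel <- function(img) {
  stopifnot(inherits(img, "scan_image"))
  if (img$channels == 1L) return(img)
  if (img$channels != 3L) {
    stop("expected 1 or 3 channels, got ", img$channels)
  }
  scan_image(img$pixels[, , 1L], dpi = img$dpi, bit_depth = img$bit_depth)
}

#' Circular region of interest
#'
#' @param center_x_mm,center_y_mm Centre in physical image coordinates (mm,
#'   origin at the top-left pixel centre).
#' @param diameter_mm Diameter in mm (> 0); the measurement protocol uses
#'   1 mm circles.
#' @param label Optional point label.
#' @return An object of class `roi_circle`.
#' @export
roi_circle <- function(center_x_mm, center_y_mm, diameter_mm = 1, label = NA) {
  stopifnot(is.numeric(center_x_mm), is.numeric(center_y_mm),
            is.numeric(diameter_mm), diameter_mm > 0)
  structure(
    list(center_x_mm = center_x_mm, center_y_mm = center_y_mm,
         diameter_mm = diameter_mm, label = label),
    class = "roi_circle"
  )
}

#' Pixel statistics inside a circular ROI
#'
#' A pixel belongs to the ROI iff its centre lies within the circle
#' (distances exactly equal to the radius are included). Returns the mean
#' and sample standard deviation of the raw pixel values, and the pixel
#' count. The circle must lie fully inside the image.
#'
#' @param img Single-channel [scan_image()].
#' @param roi A [roi_circle()].
#' @return A list of class `roi_stat` with `mean_pv`, `sd_pv`, `n_pixels`.
#' @export
roi_stats <- function(img, roi) {
  stopifnot(inherits(img, "scan_image"), inherits(roi, "roi_circle"))
  if (img$channels != 1L) stop("roi_stats needs a single-channel image")
  pitch <- 25.4 / img$dpi
  cx <- roi$center_x_mm / pitch  # 0-based pixel coordinates
  cy <- roi$center_y_mm / pitch
  r <- (roi$diameter_mm / 2) / pitch
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  if (cx - r < -0.5 || cx + r > nc - 0.5 || cy - r < -0.5 || cy + r > nr - 0.5) {
    stop("ROI outside image bounds")
  }
  jj <- max(1L, floor(cx - r) + 1L):min(nc, ceiling(cx + r) + 1L)
  ii <- max(1L, floor(cy - r) + 1L):min(nr, ceiling(cy + r) + 1L)
  dx2 <- ((jj - 1) - cx)^2
  dy2 <- ((ii - 1) - cy)^2
  mask <- outer(dy2, dx2, `+`) <= r^2 + 1e-12
  n <- sum(mask)
  if (n == 0L) stop("ROI contains no pixel centers")
  vals <- img$pixels[ii, jj, drop = FALSE][mask]
  structure(
    list(mean_pv = mean(vals),
         sd_pv = if (n > 1L) stats::sd(vals) else 0,
         n_pixels = n),
    class = "roi_stat"
  )
}

#' Read an ROI list from CSV
#'
#' Expected columns: `center_x_mm`, `center_y_mm`, `diameter_mm`, `label`.
#'
#' @param path CSV file path.
#' @return A list of [roi_circle()] objects.
#' @export
read_roi_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("center_x_mm", "center_y_mm", "diameter_mm")
  if (!all(need %in% names(df))) {
    stop("ROI table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(df$label)) df$label <- seq_len(nrow(df))
  lapply(seq_len(nrow(df)), function(i) {
    roi_circle(df$center_x_mm[i], df$center_y_mm[i], df$diameter_mm[i],
               df$label[i])
  })
}
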