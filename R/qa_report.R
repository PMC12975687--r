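#' Tolerance verdict
#'
#' Pass iff `|value - target| <= tol`.
#'
#' @param value Measured value.
#' @param target Target value.
#' @param tol Tolerance (>= 0).
#' @param check Optional label.
#' @return A list of class `qa_verdict` with `check`, `value`, `target`,
#'   `tol`, `diff` (`value - target`, exact) and logical `pass`.
#' @export
check_tolerance <- function(value, target, tol, check = NA_character_) {
  if (tol < 0) stop("tolerance must be >= 0")
  structure(
    list(check = check, value = value, target = target, tol = tol,
         diff = value - target, pass = abs(value - target) <= tol),
    class = "qa_verdict"
  )
}

#' @export
print.qa_verdict <- function(x, ...) {
  cat(sprintf("[%s] %s: value %.4g vs target %.4g (tol %.4g, diff %+.4g)\n",
              if (x$pass) "PASS" else "FAIL",
              ifelse(is.na(x$check), "check", x$check),
              x$value, x$target, x$tol, x$diff))
  invisible(x)
}

default_tolerances <- function() {
  list(ratio_pp = 2, planar_mean_pct = 5, expanded_pct = 11)
}

resolve_scan <- function(x, dpi = NULL) {
  if (inherits(x, "scan_image")) return(x)
  read_scan(x, dpi = dpi)
}

#' Run the full plaque QA pipeline
#'
#' Orchestrates densitometry, calibration, dual-depth central-axis ratio
#' verification, 33-point planar comparison and the uncertainty budget
#' into a single QA report with pass/fail verdicts.
#'
#' The `config` is a named list (or a path to a JSON file) with sections:
#' \describe{
#'   \item{model}{Plaque model name or JSON path.}
#'   \item{curve}{Path to an inverse calibration JSON, or an inverse
#'     [calibration_curve()]. Alternatively supply `calibration`: a list
#'     with `table` (data frame or CSV with `time_min`, `delta_netod`) and
#'     `rate_mGy_per_min`, fitted on the fly.}
#'   \item{scans}{`pre_1mm`, `post_1mm`, `pre_3mm`, `post_3mm` — scan
#'     paths or [scan_image()] objects — plus optional `dpi`, `p_bg`,
#'     `zero_netod`, `center_mm`.}
#'   \item{tolerances}{`ratio_pp` (dual-depth ratio, percentage points),
#'     `planar_mean_pct` (region mean |difference|), `expanded_pct`
#'     (expanded k=2 uncertainty ceiling, default the 11% certification
#'     bound).}
#'   \item{budget}{Optional: `doses_Gy`, `sd_netod`, `k`.}
#' }
#'
#' @param config Named list or JSON path.
#' @return An object of class `qa_report`: plaque name, `cax_ratio`
#'   (measured, certified, difference in pp), `planar` region summary,
#'   `budget`, and a `verdicts` data frame. `all_pass` is TRUE iff every
#'   verdict passed.
#' @export
run_qa <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("QA stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.null(config$model)) stop("config error: no plaque model")
  model <- stage("model", {
    if (inherits(config$model, "plaque_model")) config$model
    else plaque_model(config$model)
  })
  grid <- stage("grid", build_reference_grid(model))
  curve <- stage("calibration", {
    if (inherits(config$curve, "calibration_curve")) {
      config$curve
    } else if (is.character(config$curve)) {
      read_curve(config$curve)
    } else if (!is.null(config$calibration)) {
      cal <- config$calibration
      tab <- if (is.character(cal$table)) read_calibration_table(cal$table)
             else cal$table
      rate <- if (is.null(cal$rate_mGy_per_min)) 120.1 else cal$rate_mGy_per_min
      fit_inverse(tab$delta_netod,
                  delivered_dose(rate, tab$time_min))
    } else {
      stop("config error: supply `curve` or `calibration`")
    }
  })
  sc <- config$scans
  if (is.null(sc)) stop("config error: no scans section")
  p_bg <- if (is.null(sc$p_bg)) 0 else sc$p_bg
  zero <- if (is.null(sc$zero_netod)) 0 else sc$zero_netod
  tol <- utils::modifyList(default_tolerances(),
                           if (is.null(config$tolerances)) list()
                           else config$tolerances)

  planar_meas <- stage("planar", {
    post <- resolve_scan(sc$post_1mm, sc$dpi)
    pre <- resolve_scan(sc$pre_1mm, sc$dpi)
    measure_planar(post, pre, grid, curve, zero_netod = zero, p_bg = p_bg,
                   center_mm = sc$center_mm)
  })
  planar_cmp <- stage("planar", compare_planar(planar_meas, model, grid))

  center_dose <- function(pre, post) {
    m <- measure_planar(resolve_scan(post, sc$dpi), resolve_scan(pre, sc$dpi),
                        grid, curve, zero_netod = zero, p_bg = p_bg,
                        center_mm = sc$center_mm)
    m$dose_Gy[m$axis == "center"]
  }
  cax <- stage("cax_ratio", {
    d1 <- planar_meas$dose_Gy[planar_meas$axis == "center"]
    d3 <- center_dose(sc$pre_3mm, sc$post_3mm)
    measured <- dual_depth_ratio(d1, d3)
    list(dose_1mm_Gy = d1, dose_3mm_Gy = d3, measured_pct = measured,
         certified_pct = model$certified_ratio_pct,
         difference_pp = measured - model$certified_ratio_pct)
  })

  budget <- stage("budget", {
    b <- if (is.null(config$budget)) list() else config$budget
    doses <- if (is.null(b$doses_Gy)) {
      # representative doses: the measured centre doses at the two depths,
      # clamped into the calibrated window
      pmin(pmax(c(cax$dose_3mm_Gy, cax$dose_1mm_Gy),
                curve$dose_range_Gy[1]), curve$dose_range_Gy[2])
    } else b$doses_Gy
    sdn <- if (is.null(b$sd_netod)) {
      planar_meas$sd_netod[planar_meas$axis == "center"]
    } else b$sd_netod
    k <- if (is.null(b$k)) 2 else b$k
    uncertainty_budget(curve, doses, sdn, k = k)
  })

  verdicts <- list(
    check_tolerance(cax$measured_pct, cax$certified_pct, tol$ratio_pp,
                    "dual_depth_ratio")
  )
  rs <- planar_cmp$region_summary
  for (i in seq_len(nrow(rs))) {
    if (is.na(rs$mean_pct[i])) next
    verdicts[[length(verdicts) + 1L]] <- check_tolerance(
      rs$mean_pct[i], 0, tol$planar_mean_pct,
      paste0("planar_mean_", rs$region[i]))
  }
  verdicts[[length(verdicts) + 1L]] <- check_tolerance(
    max(budget$expanded_pct), 0, tol$expanded_pct, "expanded_uncertainty")

  vdf <- do.call(rbind, lapply(verdicts, function(v) {
    data.frame(check = v$check, value = v$value, target = v$target,
               tol = v$tol, diff = v$diff, pass = v$pass)
  }))
  structure(
    list(plaque = model$name, cax_ratio = cax,
         planar = list(region_summary = rs,
                       excluded_points = planar_cmp$excluded_points),
         budget = as.data.frame(budget), tolerances = tol,
         verdicts = vdf, all_pass = all(vdf$pass)),
    class = "qa_report"
  )
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("<qa_report> plaque %s - %s\n", x$plaque,
              if (x$all_pass) "ALL CHECKS PASS" else "CHECK FAILURE"))
  cat(sprintf(
    "  dual-depth ratio: %.1f%% measured vs %.1f%% certified (%+.1f pp)\n",
    x$cax_ratio$measured_pct, x$cax_ratio$certified_pct,
    x$cax_ratio$difference_pp))
  cat("  planar region summary (|diff| %):\n")
  print(x$planar$region_summary, row.names = FALSE)
  cat("  verdicts:\n")
  print(x$verdicts, row.names = FALSE)
  invisible(x)
}

#' Serialize a QA report to JSON
#' @param report A [run_qa()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qa_report <- function(report, path) {
  stopifnot(inherits(report, "qa_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a QA report from JSON
#' @param path JSON path written by [write_qa_report()].
#' @return A `qa_report` object.
#' @export
read_qa_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$planar$region_summary <- as.data.frame(obj$planar$region_summary)
  obj$verdicts <- as.data.frame(obj$verdicts)
  obj$budget <- as.data.frame(obj$budget)
  structure(obj, class = "qa_report")
}
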