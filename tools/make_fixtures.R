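# Regenerates inst/extdata/plaque_{CCA,COB,CIB}.json.
#
# Provenance of each block is recorded inside the JSON:
#  - certified_cax (CCA): the published certificate depth-dose table
#    (11 depths, normalized at 2 mm).
#  - certified_cax (COB/CIB): synthetic stand-ins. The public record gives
#    only the certified dual-depth ratios for these models, so their tables
#    are derived from the CCA profile by a power transform v^gamma with
#    gamma chosen so that v(3mm)/v(1mm) equals the certified ratio. The
#    transform preserves the 2 mm normalization (1^gamma = 1), monotone
#    decrease, and smoothness.
#  - certified_ratio_pct: published certificate values (57.0 / 58.1 / 55.3).
#  - certified_planar: synthetic stand-ins for the unpublished 33-point
#    certificates, evaluated from the model's analytic planar field at the
#    reference grid points for the standard 15-min QA exposure
#    (120.1 mGy/min -> 1.8015 Gy at the centre).
#
# Run from the package root:  Rscript tools/make_fixtures.R

devtools::load_all(".", quiet = TRUE)

cca_cax <- data.frame(
  depth_mm = c(0.83, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
  normalized_dose = c(1.35, 1.30, 1.00, 0.74, 0.52, 0.36, 0.23, 0.15,
                      0.09, 0.05, 0.03)
)

power_cax <- function(target_ratio_pct) {
  gamma <- log(target_ratio_pct / 100) / log(0.74 / 1.30)
  data.frame(depth_mm = cca_cax$depth_mm,
             normalized_dose = round(cca_cax$normalized_dose^gamma, 4))
}

defs <- list(
  CCA = list(diameter_mm = 15.3, notch = "none", point_spacing_mm = 2.55,
             certified_ratio_pct = 57.0, cax = cca_cax,
             cax_provenance = "certified",
             field = list(r05_mm = 11.5, power = 3)),
  COB = list(diameter_mm = 19.8, notch = "optic", point_spacing_mm = 3.30,
             certified_ratio_pct = 58.1, cax = power_cax(58.1),
             cax_provenance = "synthetic",
             field = list(r05_mm = 11.5, power = 3,
                          notch = list(r_start_mm = 10.5, r_end_mm = 12.5,
                                       angle_deg = 90, half_width_deg = 25,
                                       taper_deg = 10, depth = 0.97))),
  CIB = list(diameter_mm = 20.2, notch = "iris", point_spacing_mm = 3.37,
             certified_ratio_pct = 55.3, cax = power_cax(55.3),
             cax_provenance = "synthetic",
             field = list(r05_mm = 11.8, power = 3,
                          notch = list(r_start_mm = 7, r_end_mm = 9.5,
                                       angle_deg = 90, half_width_deg = 25,
                                       taper_deg = 10, depth = 0.97)))
)

center_dose <- delivered_dose(120.1, 15)  # standard 15-min QA exposure

for (nm in names(defs)) {
  d <- defs[[nm]]
  model <- structure(
    list(name = nm, diameter_mm = d$diameter_mm, notch = d$notch,
         point_spacing_mm = d$point_spacing_mm, film_radius_mm = 27.9 / 2,
         certified_cax = d$cax, certified_ratio_pct = d$certified_ratio_pct,
         certified_planar = NULL, field = d$field),
    class = "plaque_model"
  )
  grid <- build_reference_grid(model)
  f <- planar_dose_function(model, center_dose)
  model$certified_planar <- round(f(grid$x_mm, grid$y_mm), 6)
  model$provenance <- list(
    certified_cax = d$cax_provenance,
    certified_ratio_pct = "certified",
    certified_planar = "synthetic",
    planar_exposure = sprintf("15 min at 120.1 mGy/min (%.4f Gy centre)",
                              center_dose)
  )
  out <- file.path("inst", "extdata", paste0("plaque_", nm, ".json"))
  jsonlite::write_json(unclass(model), out, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  cat("wrote", out, "\n")
}
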