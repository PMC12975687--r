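---
title: "Methods: film dosimetry QA for Ru-106 eye plaques"
author: "plaquefilm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: film dosimetry QA for Ru-106 eye plaques}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`plaquefilm` implements the analysis side of a radiochromic-film quality
assurance workflow for Ru-106 ophthalmic applicators (eye plaques): scanned
films are converted to dose through a power-law optical-density calibration,
and the resulting doses are checked against manufacturer-certified reference
data — a dual-depth central-axis (CAX) dose ratio, an 11-depth certified
depth-dose table, and a 33-point planar reference grid. The package does not
model film chemistry, holder mechanics, or beta transport; its inputs are
scan rasters, irradiation schedules and certificate tables.

## Densitometry model

A film reading pairs the red-channel mean pixel values of one circular
region of interest (ROI) before (`P0`) and after (`P`) irradiation, with a
per-session background level `Pbg`:

    netOD = log10( (P0 - Pbg) / (P - Pbg) )

Orientation is chosen so netOD grows with dose (the film darkens,
`P < P0`), consistent with the Devic radiochromic-film formalism; the
opposite sign convention is available via an argument for forensic
comparison of analyses that used it. `Pbg` is a single scalar per scan
session, defaulting to 0 when no opaque/zero-reflectance reading exists;
whether it is measured from an opaque strip or an empty-bed region is an
acquisition choice the package deliberately leaves to the operator.

Each film's netOD is re-zeroed against an unirradiated control film scanned
in the same session (`delta_net_od()`), anchoring the response at
(0 Gy, 0). First-order error propagation gives

    SD_netOD = (1/ln 10) * sqrt( SD_P0^2/(P0-Pbg)^2 + SD_P^2/(P-Pbg)^2 )

By default the `SD_P` terms are the ROI pixel-value standard deviations,
exactly as the propagation formula is written; dividing by `sqrt(n_pixels)`
(standard-error semantics, appropriate when the quantity of interest is the
uncertainty of the ROI *mean*) is available through `se = TRUE` in
`reading_from_rois()`. The pixel-SD default is deliberately conservative.

ROI statistics use a center-in rule: a pixel belongs to the circle iff its
centre lies within the radius (ties included). The rule is deterministic and
brute-force checkable; the tests verify it against an exhaustive
pixel-enumeration oracle. Physical coordinates put the origin at the centre
of the top-left pixel with `mm = index * 25.4 / dpi`; no image registration
is performed — alignment is the acquisition protocol's job, and an explicit
`center_mm` offset is accepted wherever a grid is placed on an image.

## Calibration

The delivered dose is `rate x time / 1000` Gy, with the dose rate obtained
by half-life decay correction of the certified reference rate
(`rate * 2^(-elapsed/373.6 d)` for Ru-106). The reference schedule
irradiates for 2.5, 5, 10, 15 and 20 min at 120.1 mGy/min, spanning roughly
0.3-2.4 Gy.

Dose response is modelled in both directions by the same two-term power-law
family with *independent* parameter sets:

    forward:  dnetOD = a*D + b*D^n
    inverse:  D = a*dnetOD + b*dnetOD^n

The inverse form is fitted directly on the calibration points (never
obtained by numerically inverting the forward fit) and is the curve used for
dose conversion. A `form` flag keeps the two parameter sets from ever being
interchanged.

Fitting is unweighted least squares (a weights argument exists for
sensitivity checks; whether the original workflow weighted by netOD SDs is
unknowable from the public record, so unweighted is the default). The
exponent is profiled: for fixed `n` the model is linear in `(a, b)`, so a
coarse grid over `n` in (1, 5] followed by golden-section refinement finds
the global optimum deterministically, with no start-point sensitivity. An
exact (0, 0) anchor is appended when absent, reflecting the zero-dose
normalization. Parameter SDs come from the two-parameter covariance of
`(a, b)` with `n` held at its estimate — the downstream uncertainty formulas
use only `SD_a` and `SD_b`, treat the parameters as uncorrelated and `n` as
exact, and the Monte-Carlo oracles in the tests make the same assumptions so
that the equivalence check is well posed. Residual degrees of freedom count
all three estimated parameters.

### The inverse-family floor

The inverse of a two-term power law is not itself a two-term power law.
Composing the exact forward response with a fitted inverse therefore carries
an irreducible model error even on noise-free data: for the synthetic truth
`(a, b, n) = (0.08, 0.02, 1.8)` the maximum relative error over the
calibrated range is about 0.55% (about 1.4% for steeper parameter sets),
concentrated at the 0.3 Gy end and present at the fitted points themselves.
This is a property of the model family, not of the fitting algorithm —
parameter recovery on data generated *from the inverse family itself* is
exact to 1e-4 relative. Relative-error weighting (`weights = 1/D^2`) roughly
halves the floor and is available behind the weights argument. The tests
assert these computed bounds; real film data, which is only approximately
power-law in either direction, absorbs the discrepancy into its fit
residuals.

Conversion refuses delta-netOD below `-1e-6` (noise around zero is clamped
to 0) and warns when the implied dose leaves the calibrated window. No
extrapolation below the smallest calibration dose is performed anywhere: the
uncertainty budget errors out rather than extrapolating.

## Uncertainty budget

Percentages are of the fitted dose `D_fit` at the measured `x = dnetOD`:

    SD_fit% = 100 * sqrt( x^2 SD_a^2 + x^(2n) SD_b^2 ) / D_fit
    SD_exp% = 100 * (a + n b x^(n-1)) * SD_netOD / D_fit
    SD_tot% = sqrt( SD_exp%^2 + SD_fit%^2 )
    U(k)    = k * SD_tot%        (k = 2 for ~95% coverage)

Both components are undefined at zero dose (0/0) and error accordingly.
`uncertainty_budget()` evaluates the chain at stated doses by numerically
inverting the fitted curve (bisection on the monotone response). The
headline QA criterion is that the expanded `k = 2` uncertainty stays below
the ±11% bound typical of manufacturer certificates; `run_qa()` evaluates
the budget at the doses actually measured (the two centre doses, clamped
into the calibrated window) rather than at the range endpoints, since with
pixel-SD semantics the 0.3 Gy budget is a worst case irrelevant to a
measurement taken near 1.8 Gy.

## Central-axis analysis

Certificates list the CAX depth dose at 11 depths (0.83-10.00 mm) derived
from a quartic polynomial, normalized to 1 at 2 mm. Measured profiles
(e.g., a microdiamond detector scanned 1.5-10.5 mm in 1 mm steps) are
fitted with the same degree-4 polynomial, evaluated at the certified
depths, and normalized by the fitted value at 2 mm. Evaluation is allowed
up to 1 mm beyond the fitted span — the certificate's shallowest point lies
just below the shallowest physically measurable detector depth — and
refused beyond that. The detector's air gap and sensitive-volume offset are
handled as one scalar depth offset applied before fitting (default 0:
depths assumed already corrected).

Per-depth differences are **percentage points of normalized dose**,
`(measured - reference) * 100`, not relative percent: on the published
comparison table the 4 mm row (0.52 vs 0.54) prints as 1.93, consistent
only with the percentage-point definition applied to unrounded values. A
`relative = TRUE` flag exists for sensitivity checks. Summary SDs use the
population divisor (N): with 11 depths this reproduces the published 0.58
(the sample divisor would give 0.61).

The dual-depth ratio — the 3 mm dose as a percentage of the 1 mm dose,
`100 * D(3mm)/D(1mm)` — is the steepness index checked against the
certificate value (mid-50s percent for these beta sources).

## Planar analysis and the reference grid

The 33 certified points are laid out as one centre point plus 8 points per
axis (x, y, and diagonals d1, d2) at signed multiples 1-4 of the per-model
spacing. Nested regions follow per-axis index: R1 is the centre plus
`|i| <= 2` (17 points), R2 adds `|i| = 3` (25 cumulative), R3 adds
`|i| = 4` (33). This is the unique per-axis assignment consistent with the
published cumulative counts under a 4-axis layout. Spacing is interpreted
along the flattened-film (arc-length) coordinate. Published data give only
the spacing range 2.55-3.37 mm; the per-model defaults fix the endpoints to
the smallest (CCA, 2.55) and largest (CIB, 3.37) plaques with COB at
3.30 mm — configuration constants, not measured values.

Points receiving less than 5% of the maximum dose are excluded; the filter
is applied to the *reference* doses so the excluded set is reproducible
regardless of measurement noise, and the boundary (exactly 5%) is kept.
Per-point planar differences are relative percent (the doses are absolute,
unlike the normalized CAX profiles), and region summaries aggregate
*absolute* differences cumulatively (R2 contains R1's points), matching the
monotone published n = 17/25/33 structure; published region means are
positive with SDs smaller than the means, which is consistent with
absolute-difference summaries and not with signed ones.

## Synthetic data generator

The generator exists so every pipeline stage is testable without physical
films. It emulates:

* the red-channel film response: per pixel,
  `dnetOD = a D + b D^n` (fixed forward truth `a = 0.08, b = 0.02,
  n = 1.8`, giving dnetOD 0.03-0.29 over 0.3-2.4 Gy, the working range of
  reflection densitometry), inverted to
  `P = Pbg + (P0 - Pbg) 10^(-dnetOD)`;
* scanner statistics: 300 dpi, 16-bit quantization, pre-irradiation level
  40000 over a 1000 background, additive Gaussian pixel noise of SD 200
  (0.5% of the pre-irradiation level), independent per pixel and identical
  in level for pre and post scans;
* plaque dose fields: a radially symmetric super-exponential fall-off
  `exp(-ln 20 (r/r05)^3)` crossing 5% of the central dose at `r05`
  (11.5 mm for CCA/COB, 11.8 mm for CIB), with an attenuating notch sector
  for the notched models. The notch parameters are set so the 5% filter
  reproduces the characteristic kept-point patterns: all 33 points for
  CCA, the outermost ring excluded for COB/CIB, and one additional
  intermediate point lost under the CIB iris notch (17/24).

One integer seed fixes all randomness; identical specs give bit-identical
TIFF pairs. The generator does **not** model scanner point-spread or
lateral-response nonuniformity, spatially correlated film grain,
post-exposure darkening kinetics, the arc-versus-chord geometric distortion
of flattening a curved film, or real beta transport. Passing tests
therefore demonstrate the correctness of the analysis chain under the
stated noise model — not the physical accuracy of any film system.

Because the forward truth and the fitted inverse live in different
parameterizations, the end-to-end recovery test is a genuine estimation
problem, not an identity check.

### Certificate stand-ins

The published record contains the full certified CAX table only for the
CCA model. The bundled COB and CIB tables are synthetic stand-ins derived
from the CCA profile by a power transform `v^gamma` with `gamma` chosen so
the 1 mm/3 mm ratio equals each model's certified ratio (58.1%, 55.3%);
the transform preserves the 2 mm normalization, monotone decay and
smoothness. The 33-point certified planar dose vectors are not public for
any model; the bundled vectors are the analytic field evaluated at the
grid points for a 15-min exposure at 120.1 mGy/min. All stand-ins carry
`provenance` fields inside the fixture JSON (`tools/make_fixtures.R`
regenerates them).

## Numerical choices and degenerate inputs

* Exponent bounds (1, 5]; grid step 0.01 then golden-section to 1e-10.
* Calibration requires at least 4 distinct user points before the
  automatic anchor, and strictly monotone data (sorted by x, y must not
  decrease) — otherwise "calibration not monotone".
* The quartic fit requires 5 or more distinct depths and interpolates
  exactly at 5; duplicate depths are refused.
* ROI circles must lie fully inside the image; a circle containing no
  pixel centre is an error, not an empty statistic. ROI SDs use the sample
  divisor with the n = 1 case defined as 0.
* All-zero dose vectors are refused by the 5% filter ("no signal");
  filtering is scale-invariant and always keeps the maximum.
* The synthetic forward model refuses responses whose quantized signal is
  indistinguishable from background ("response saturated").
* Negative elapsed decay times (pre-certification dates) warn rather than
  error, supporting certificate cross-checks.

## Problem sizes used by the test-suite

Simulated scans are 30 mm square at 300 dpi (355 x 355 px, 16-bit);
calibration films are 4 mm uniform patches; Monte-Carlo oracles use 1e5
draws; the noisy-recovery property uses 200 replicate fits; the
noise-monotonicity property uses 50 seeds per noise level. These sizes make
the full suite run in well under a minute while leaving every statistical
tolerance comfortably resolved.

## Known limitations

* Single-batch, single-session calibration only: no batch transfer,
  re-scan drift correction, or darkening-kinetics model.
* No multichannel (triple-channel) dosimetry, scanner lateral-response
  correction, or automatic fiducial detection.
* No gamma-index or distance-to-agreement analysis, no 2D interpolation
  between grid points, and no arc-to-chord geometric correction — the
  flattened-film coordinate convention is documented instead.
* Uncertainty formulas treat `(a, b)` as uncorrelated and `n` as exact;
  they are first-order and inherit the usual small-noise caveats, which
  the Monte-Carlo equivalence tests make explicit.
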