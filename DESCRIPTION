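Package: plaquefilm
Title: Film Dosimetry Quality Assurance for Ru-106 Eye Plaques
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for radiochromic-film quality assurance of
    Ru-106 ophthalmic applicators (eye plaques). Converts scanned-film
    red-channel pixel values to net optical density, fits forward and
    inverse power-law dose-response calibrations with a propagated
    uncertainty budget (experimental, fitting, and expanded k = 2
    components), performs quartic central-axis depth-dose analysis against
    certified reference tables, verifies the dual-depth (1 mm / 3 mm) dose
    ratio, and compares 33-point planar dose distributions by nested
    radial region. Includes a synthetic scan generator that emulates the
    film response over known dose fields so the whole pipeline is testable
    without physical films.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
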