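Package: afmwv
Title: Work-of-Indentation Analysis for AFM Force Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of atomic force microscopy (AFM) nanoindentation data on
    soft and biological samples using the work done by the indenter per unit
    contact volume (W/V). Converts raw load-displacement records to
    load-indentation curves, tests whether a sample behaves as a linear elastic
    half-space via the linearity of work against the cube of indentation depth,
    estimates Young's modulus both by Sneddon fitting and by the W/V route,
    characterises depth-dependent mechanics with a polynomial W/V profile, and
    produces spatial mechanical-property maps with summary statistics. Includes
    a synthetic force-curve generator with known ground truth for validation,
    unit-aware text I/O, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
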