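Package: sbftiming
Title: Striatal Beat-Frequency Model of Interval Timing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the striatal beat-frequency
    (SBF) model of interval timing. Provides banks of cosine phase oscillators
    and dimensionless Morris-Lecar conductance-based neurons, coincidence
    detection of running against memorised oscillator states, closed-form
    Dirichlet-kernel output functions, and the envelope analyses that show how
    criterion-time (memory) noise turns a constant-width, scalar-property
    violating readout into a Gaussian response whose width grows linearly with
    the timed duration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    utils,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
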