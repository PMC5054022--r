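Package: crpg
Title: Hodgkin-Huxley Modelling and Virtual Electrophysiology of
    Calretinin-Positive Periglomerular Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-compartment Hodgkin-Huxley model of calretinin-positive
    periglomerular interneurons of the mouse olfactory bulb, together with a
    virtual-electrophysiology protocol engine (current clamp and ideal voltage
    clamp) and the voltage-clamp analysis procedures used to characterize
    these cells: single-exponential passive fits, zero-time extrapolation of
    decaying currents, Boltzmann activation/inactivation fits, double-pulse
    recovery-from-inactivation analysis, h-current tail analysis, and
    paired-pulse excitability batteries. Includes a synthetic-data generator
    (recording noise, cell-to-cell parameter variability) so every analysis
    stage is testable by parameter recovery on simulated recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
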