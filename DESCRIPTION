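Package: striatr
Title: Biophysical Simulation of Striatal Microcircuit Rhythms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Conductance-based (Hodgkin-Huxley type) simulation of striatal
    microcircuits built from two-compartment fast-spiking interneurons (FSIs)
    carrying a D-type potassium current and single-compartment spiny projection
    neurons (SPNs) carrying an M-current, coupled by GABA-A synapses and
    dendro-dendritic gap junctions. Includes dopamine-dependent parameter
    regimes, a fixed-step fourth-order Runge-Kutta network integrator with
    Poisson and Gaussian background drives, and an analysis layer: surrogate
    local field potential (summed synaptic currents), multitaper spectra and
    spectrograms, burst statistics, minimum-firing-rate estimation, Morlet
    wavelet band traces, and phase-amplitude modulation summaries. Reproduces
    the interleaving of gamma and beta oscillations at delta/theta timescales
    across dopaminergic conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    yaml,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    patchwork
Config/testthat/edition: 3
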