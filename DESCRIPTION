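Package: filakin
Title: Stochastic Growth Kinetics of Two-Ended Supramolecular Filaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the elongation and shortening kinetics of
    supramolecular peptide filaments (diphenylalanine-class nanotubes) observed
    one assembly at a time under microfluidic concentration control. Provides
    an exact Gillespie simulator of a two-ended filament with independent
    attachment, detachment and capping kinetics per terminus, in an open bath
    (continuous flow, constant monomer concentration) or a closed pool (finite
    reservoir relaxing to equilibrium at the critical concentration);
    estimation of the linear growth law R = k_on * c - k_off and the critical
    concentration c_s = k_off / k_on from length time series; a per-terminus
    directionality classifier (unidirectional versus bidirectional growth);
    laminar co-flow mixing arithmetic for programming in-channel
    concentrations; and a synthetic-data generator emulating frame-sampled,
    replicate-averaged microscopy length measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
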