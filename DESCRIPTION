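Package: netlr
Title: Linear Response Theory for Heterogeneous Recurrent Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for computing firing rates and pairwise spike-count
    correlations in heterogeneous, recurrently coupled conductance-based
    integrate-and-fire networks. Implements Fokker-Planck threshold
    integration for steady-state rates, susceptibility functions and
    spike-train power spectra of an effective single-neuron equation;
    a damped self-consistent solver for network firing rates; the
    linear-response cross-spectrum with its motif expansion and
    second-order motif-type decomposition; a reduced two-parameter
    firing-rate surface with correlation-susceptibility, path, and
    gradient-alignment analysis; parameter-family sweeps; and a
    Monte Carlo network simulator with spike-count statistics for
    validating the theoretical outputs.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    parallel
Config/testthat/edition: 3
RoxygenNote: 7.3.3
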