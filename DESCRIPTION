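Package: seizprop
Title: Seizure Propagation on Brain Networks and Its Bayesian Inversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data-driven model of epileptic seizure recruitment and
    propagation across a weighted structural brain network, together with
    the machinery to invert it from partially observed region onset times.
    Provides an exact event-driven simulator of accumulate-to-threshold
    dynamics with analytic forward sensitivities, a No-U-Turn Hamiltonian
    Monte Carlo sampler for single-seizure and hierarchical multi-seizure
    inference, SEEG channel onset detection and channel-to-region mapping,
    connectome normalization, leave-one-out validation with estimator
    baselines, precision-recall scoring against resections, virtual
    resection, permutation feature importance, and synthetic-data
    generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
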