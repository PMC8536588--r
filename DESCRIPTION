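Package: hajmsm
Title: Hybrid Landmark Aalen-Johansen Estimation for Partially
    Non-Markov Multi-State Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nonparametric estimation of transition probabilities in
    multi-state models that are Markov for some transitions and
    non-Markov for others.  Implements the Aalen-Johansen (AJ) estimator,
    the landmark Aalen-Johansen (LMAJ) estimator, and the hybrid landmark
    Aalen-Johansen (HAJ) estimator that uses landmark Nelson-Aalen rates
    only for a selected set of non-Markov transitions.  Provides
    transition-wise log-rank tests of the Markov property (point test and
    landmark-grid test) calibrated by a wild bootstrap with standardized
    compensated Poisson multipliers, nonparametric bootstrap variance and
    percentile intervals, a Greenwood-type plug-in variance, a
    frailty-driven simulator for the illness-death model with recovery,
    and evaluation utilities (mean residual squared error, pointwise bias
    and variance, interval coverage).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
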