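Package: neutralcr
Title: Emergent Neutrality in Stochastic Consumer-Resource Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exact event-driven (Gillespie) simulation of a stochastic
    consumer-resource community with a speciation floor, together with the
    deterministic mean-field theory (Jacobian spectra, niche/neutral
    threshold predictions), closed-form neutral baselines (Fisher log-series
    species abundance distribution, drift extinction times, abundance
    fluctuation variance), and the statistical machinery used to decide
    whether a simulated community is distinguishable from neutrality:
    a discrete Cramer-von Mises goodness-of-fit test with parametric
    bootstrap, logistic threshold regression, extinction-time binning, and
    consumption-event preference-cosine estimation. Experiment drivers
    orchestrate ensemble scans over the generalist and specialist
    non-neutrality scenarios and return tidy tibbles ready for dplyr and
    ggplot2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
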