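Package: stagemap
Title: Small-Area Disease Mapping of Stage-Specific Cancer Incidence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for monitoring inequalities in early cancer detection by
    mapping stage-specific incidence over small areas. Implements direct and
    indirect age-sex standardisation, Besag-York-Mollie (BYM) Bayesian spatial
    smoothing of standardised incidence ratios by Markov chain Monte Carlo,
    posterior-probability signal classification, weighted ecological regression
    of smoothed incidence on small-area deprivation quintiles, case-level
    late-stage logistic regression, a purely spatial Poisson scan statistic,
    and a synthetic-data generator that emulates registry case, population and
    geography inputs so the full pipeline can be exercised without access to
    confidential registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
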