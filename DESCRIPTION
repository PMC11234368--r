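Package: clonebd
Title: Birth-Death Modeling of Clonal Lineage-Tracing Data
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of pulse-chase clonal lineage-tracing experiments with
    linear birth-death models whose rates may change with clonal age.  Provides
    data structures and summary statistics for per-clone basal/suprabasal cell
    counts, closed-form propagation of time-inhomogeneous (piecewise-constant)
    birth-death processes, geometric clone-size laws for neutral competition
    and their neutral-drift limit, homeostatic steady-state structure of
    non-self-renewing transit-amplifying populations, an exact Gillespie
    simulator and cross-sectional experiment generator, and estimation tools:
    division-interval and half-life estimators, critical and generalized
    birth-death model fits with labeling-bias variants, likelihood-ratio model
    selection, and goodness-of-fit tests for neutral competition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    pracma,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
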