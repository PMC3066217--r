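Package: ovasig
Title: Integrative Multi-Cohort Prognostic Signatures for Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and validates multi-gene prognostic signatures from
    several gene expression cohorts. Cohorts are quantile-normalized,
    quality-controlled, merged on shared genes and adjusted for batch
    effects with a location/scale empirical-Bayes model. A supervised
    principal-component survival classifier is fit on survival-screened
    genes, risk groups are assigned by leave-one-out cross-validation and
    tested by permutation, and fitted models transfer to co-adjusted
    validation cohorts. Risk phenotypes are characterized by subclass
    mapping between cohorts (mutual marker-gene enrichment), maxmean
    gene-set analysis, jackknifed over-representation scoring, and
    Bayesian probit pathway-activation probabilities trained on on/off
    perturbation arrays. A synthetic-data module generates multi-batch
    studies with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    sva
Config/testthat/edition: 3
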