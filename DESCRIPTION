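Package: bmlmm
Title: Bayesian Two-Level Latent Moderated Mediation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gibbs sampling for two-level (1-1-1) latent mediation models with
    random a and b paths and an observed cluster-level moderator, under two
    algebraically equivalent parameterizations: random coefficient prediction
    (the moderator predicts the random slopes) and latent interaction (the
    moderator enters through cross-level product terms). Provides a seeded
    synthetic-data generator matching the model, Gelman-Rubin convergence
    diagnostics with automatic chain extension, posterior conditional indirect
    effects with percentile credible intervals, posterior-overlap model
    comparison, and a Monte Carlo harness for type-I error, power and relative
    bias.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
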