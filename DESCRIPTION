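Package: polycomp
Title: Information-Theoretic Comparison of Constrained Polynomial
    Trait-Outcome Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Competitive testing of substantive hypotheses about how two
    personality traits (extraversion and neuroticism) jointly predict
    loneliness, phrased as constraint systems on the coefficients of a full
    second-order polynomial regression surface.  Provides a fixed catalogue
    of 19 candidate models (linear, saturating and exponential main-effect
    shapes, mutual-compensation and optimal-constellation interaction
    surfaces, null and full models), exact constrained maximum-likelihood
    estimation with full-information handling of missing follow-up
    outcomes, AICc-based multimodel inference (Akaike weights, redundancy
    pruning of nested models, 95% confidence sets, evidence ratios),
    response-surface interpretation restricted to the observed data region,
    influence screening, a-priori power simulation for the omnibus
    full-vs-null test with a noncentral-F oracle, and a synthetic cohort
    generator for model- and parameter-recovery experiments.
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
    MASS,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
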