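Package: hetmctp
Title: Multiple Contrast Tests for Heteroscedastic ANCOVA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Covariate-adjusted multiple contrast test procedures (MCTPs) for
    general factorial designs under variance heteroscedasticity. Treatment
    effects are estimated in a heteroscedastic ANCOVA model with sandwich
    covariance estimators, either with group-wise variances (Behrens-Fisher
    setting) or with subject-wise variances (complete heteroscedasticity,
    White's estimator). Small-sample inference for max-type contrast
    statistics uses a multivariate t approximation with Box-type
    (Satterthwaite) degrees of freedom, or a wild bootstrap with Rademacher
    weights. Compatible simultaneous confidence intervals, Dunnett, Tukey,
    grand-mean and Kronecker factorial contrasts, and a Monte-Carlo engine
    for type-I-error and power studies are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    mvtnorm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
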