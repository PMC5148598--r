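Package: gwaring
Title: Generalized Waring Regression for Overdispersed Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maximum-likelihood fitting of the generalized Waring regression
    model for overdispersed counts, a beta-negative-binomial regression with
    log link that extends the negative binomial model. Provides the
    univariate generalized Waring distribution (probability mass, moments,
    random generation), Wald and likelihood-ratio inference, stepwise model
    selection by AIC or BIC, prediction with offsets, a three-way partition
    of the response variance into randomness, liability and proneness
    components, Pearson, deviance and response residuals with simulated
    normal-plot envelopes via parametric bootstrap, synthetic data
    generation from the model's latent Poisson-gamma-beta hierarchy, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    parallel,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
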