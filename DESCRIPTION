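Package: ancovapower
Title: Exact Power Analysis and Sample Size Planning for ANCOVA Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Power analysis and sample-size determination for general linear
    hypothesis (Wald) tests of treatment effects in one-way analysis of
    covariance with random covariates. Implements the exact power function in
    which the noncentrality parameter of the noncentral F distribution is
    mixed over a Beta law induced by multinormal covariates, alongside the
    conventional approximate (Cohen-style) ANCOVA method and the ANOVA
    reference method. Also provides the data-level Wald test with adjusted
    means, an iterative minimum sample-size search under allocation ratios,
    and a Monte-Carlo engine for validating power and type-I error under
    normal and non-normal covariate models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
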