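Package: vocalconverge
Title: Contact-Call Individuality and Vocal Convergence in Dyadic Social Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulation and analysis pipeline for studying vocal convergence in
    the frequency-modulated contact calls of group-living bats. Generates
    synthetic ultrasonic recordings with known individual call signatures and
    social structure; detects and filters calls; extracts 35 spectro-temporal
    and fundamental-contour acoustic features per call; quantifies caller
    similarity from Mahalanobis distances between caller centroids of a linear
    discriminant analysis; fits Bayesian beta and Gaussian multi-membership
    regressions for dyadic call similarity with kinship, co-housing and
    affiliation predictors; and tests pre/post-introduction convergence with
    Mantel tests and permuted discriminant analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    signal,
    rjags,
    coda,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
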