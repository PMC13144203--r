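Package: nmftopics
Title: Maximum-Likelihood Topic Models via Poisson Non-Negative Matrix
    Factorization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits multinomial topic models to sparse count matrices
    (document-term or cell-gene) by maximum likelihood or MAP, by solving
    the equivalent Poisson non-negative matrix factorization problem.
    The alternating Poisson regression driver supports expectation-
    maximization (multiplicative) and coordinate-descent Newton inner
    solvers, adaptive extrapolation acceleration, and the exact change of
    variables that converts a Poisson NMF fit into topic-model parameter
    estimates. Includes synthetic-data generators with known ground
    truth, topic matching utilities, fit serialization, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
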