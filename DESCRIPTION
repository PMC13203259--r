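Package: wepa
Title: Word Embedding Projection Scoring and Panel Validation for Text-Based Psychometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures psychological constructs in short texts by projecting mean
    word vectors onto bipolar semantic axes built from anchor-word dictionaries
    in a static embedding space. Provides anchor screening and pole diagnostics,
    a dictionary-ratio baseline with coverage reporting, orthogonal Procrustes
    alignment of period-specific embedding spaces with axis-stability and
    anchor rank-order-consistency indicators, construction of user-week panels
    from raw post streams, individual fixed-effects criterion-validity
    regressions with user-clustered standard errors, semi-elasticity and
    minutes-equivalent effect translation, anchor-perturbation and textual
    sparsity robustness sweeps, and SIMEX simulation-extrapolation correction
    for measurement error in projection scores. A seeded synthetic-fixture
    generator produces embedding spaces with planted bipolar axes, anchored
    corpora, and behavioral panels with known effect sizes for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
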