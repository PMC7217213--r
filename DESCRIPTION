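Package: cnma
Title: Frequentist Component Network Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frequentist network meta-analysis (NMA) and component network
    meta-analysis (CNMA) for multicomponent interventions, estimated by
    weighted least squares with Moore-Penrose pseudoinverses. Implements the
    standard (full interaction) NMA model, additive and two-way interaction
    CNMA models with common or random effects, Cochran-Q based tests of the
    additivity assumption and of nested component models, a method-of-moments
    between-study variance estimator with multi-arm adjustment, and CNMA
    estimation for disconnected networks via the estimable component
    contrasts. Includes a synthetic-network generator with known additive or
    interaction truth for calibration studies, tidy accessors, forest-style
    plots, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    MASS,
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
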