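Package: pemretro
Title: Phylogenetic Eigenvector Map Regression and Fossil Trait Retrodiction
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds phylogenetic eigenvector maps (PEMs) from rooted,
    edge-weighted trees via the tips-by-edges influence matrix, fits linear
    models combining histometric co-predictors with forward-selected
    eigenvectors (AICc stopping rule, Holm-Sidak multiple-testing
    adjustment across candidate models), and retrodicts continuous traits
    such as red blood cell size at fossil tips whose response values are
    unobserved.  Includes a seeded synthetic-data generator (pure-birth
    trees, Brownian-motion traits, noisy linear proxies, fossil masking)
    so the whole pipeline is testable without external data, and a small
    command-line interface (simulate, fit, predict, reproduce).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
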