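Package: covscreen
Title: Quantitative Analysis of Covalent Calmodulin-Inhibitor Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-style toolkit for the quantitative analysis layer of
    plate-based covalent inhibitor screening campaigns against calmodulin.
    Provides control-based normalization of plate-reader signals,
    four-parameter log-logistic dose-response fitting with closed-form
    area-under-curve and drug sensitivity scores (DSS1/DSS2/DSS3),
    competitive fluorescence-polarization binding analysis with exact
    IC50-to-Kd depletion correction, covalent inhibition kinetics
    (per-concentration kobs, global Ki and k2, second-order rate k2/Ki),
    BRET donor-saturation titration analysis (BRETmax, BRET50, assay-window
    selection, percent-inhibition traces), a composite drug activity score
    for compound ranking, and seeded synthetic-data generators emulating
    every assay so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
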