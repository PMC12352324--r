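Package: dyadik
Title: Actor-Partner Interdependence Models and Dyadic Pattern Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dyadic analysis of paired psychological measurements:
    scoring of the 14-item Perceived Stress Scale and the Edinburgh Postnatal
    Depression Scale, paired descriptive statistics, maximum-likelihood
    estimation of the four-variable Actor-Partner Interdependence Model (APIM)
    from raw couple data or summary moments, ratio-tied (phantom-variable)
    estimation of the partner/actor ratio k with bootstrap confidence
    intervals, standard structural-equation fit indices (CFI, TLI, RMSEA,
    SRMR), and a flowchart classifier of dyadic patterns (actor-only,
    couple-oriented, contrast). A synthetic-couple generator with known path
    structure supports validation of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    sandwich,
    lmtest,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
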