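Package: stabmeta
Title: Meta-Prediction of Protein Stability Changes upon Single-Point Mutation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curates single-point-mutation stability (ddG) datasets, encodes
    local sequence context together with the categorical calls of several
    element predictors into one-hot feature vectors, and trains a radial-basis
    support vector machine integrator that classifies mutations as stabilizing
    or destabilizing (plus a support vector regressor for the ddG value).
    Includes a majority-voting baseline, stratified evaluation by secondary
    structure, relative solvent accessibility, protein superfamily and
    experimental conditions, label-stratified k-fold cross-validation, a
    window-size sweep, and a synthetic element-predictor simulator so the
    whole pipeline is testable without querying any external service.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
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
    utils,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
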