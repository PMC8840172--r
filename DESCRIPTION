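Package: nutriclr
Title: Compositional Nutrient Diagnosis for Orchard Fertilization Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for compositional nutrient diagnosis in perennial fruit
    crop fertilization trials. Foliar nutrient concentrations are treated as
    compositions and analysed on the centered log-ratio (clr) scale with an
    explicit filling value; growing degree-day, chilling-hour and rainfall
    indices summarise each season; cross-validated classifiers split
    specimens into high and low performance at agronomic cutoffs; nutrient
    standards (clr norms, back-transformed concentration ranges, sufficiency
    ranges and linear-plateau critical values) are derived from the
    high-performing "true negative" population; and dose-response,
    variance-partition and season-carryover stages quantify the fertilizer
    response. A synthetic trial generator with known ground truth makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    class,
    glmnet,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
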