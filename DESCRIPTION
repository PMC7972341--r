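Package: markerpair
Title: Exploratory Evaluation and Discovery of Dual-Biomarker Combinations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates pairs of clinical biomarkers against a binary response
    and/or a time-to-event outcome through a family of four nested regression
    models (each single marker, the additive pair, and the pair with
    interaction), compared by likelihood-ratio tests. Provides median or
    user-cutoff dichotomization with R1-R4 quadrant stratification,
    Kaplan-Meier and conditional Kaplan-Meier summaries with log-rank tests,
    ROC/AUC with DeLong confidence intervals, the Gonen-Heller concordance
    probability estimate for Cox models, exact binomial response-rate
    intervals, and de-novo search for biomarker partners ranked by
    nested-model p-values with Benjamini-Hochberg adjustment. A synthetic
    cohort generator with known logistic and proportional-hazards structure
    supports calibration and power checks, and a command-line interface
    drives the pair-report and search workflows on delimited patient tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    pROC,
    dplyr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
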