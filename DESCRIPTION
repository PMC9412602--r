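Package: ironmr
Title: Two-Sample Mendelian Randomisation for Systemic Iron Status and
    Heart Failure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Instrument selection, harmonisation and causal-effect
    estimation for two-sample Mendelian randomisation from GWAS summary
    statistics, built around the analysis of four systemic iron status
    biomarkers (ferritin, serum iron, transferrin, transferrin
    saturation) and heart failure risk. Provides the Wald-ratio,
    fixed- and random-effect inverse-variance-weighted, MR-Egger and
    weighted-median estimators; heterogeneity, pleiotropy and
    leave-one-out sensitivity diagnostics; Bayesian-model-averaged
    multivariable MR with per-variant outlier and influence diagnostics
    and iterative instrument exclusion; multivariable IVW regression
    with collinearity checks; and a synthetic summary-statistic
    generator with known ground truth for calibration studies. All
    user-facing functions take data frames and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
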