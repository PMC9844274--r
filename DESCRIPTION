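Package: lineens
Title: Individual Differences in Ensemble Perception of Line Length and
    Orientation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying individual differences in ensemble
    perception with line stimuli. Generates constrained line-ensemble
    designs (factorial mean/SD structure on discrete value grids with
    exact sample means), simulates five-alternative forced-choice
    observer cohorts with a correlated latent-ability structure,
    scores trial-level errors, screens participants by chance-level
    accuracy and person-fit to trial difficulty, estimates Cronbach's
    alpha reliability, and performs one-sided Bayesian correlation
    tests (stretched-beta prior), attenuation-corrected correlations,
    and sequential Bayes-factor stopping designs.
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
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
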