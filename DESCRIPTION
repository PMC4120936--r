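Package: ethnoindices
Title: Quantitative Ethnobotany Indices and Intracultural Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes freelist-based Composite Salience and interview-based
    Cultural Importance indices for plant species, stratifies them by actor
    group (sex, age class, migration history), and provides the statistical
    machinery used to detect intracultural variation in plant knowledge:
    one-way ANOVA on arcsine-square-root transformed indices with
    Tukey-Kramer post-hoc comparisons, two-sample proportion tests per
    use-category, Spearman concordance of the two indices, Poisson and
    quasi-Poisson ANCOVA-style models of use-type counts with
    stepwise-backward simplification by likelihood-ratio or F tests, and
    Poisson mixed models with crossed participant and species random
    intercepts. Includes a synthetic interview-data generator emulating a
    balanced sex-by-age survey design so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    lme4,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
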