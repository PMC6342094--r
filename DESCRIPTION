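Package: ciconflict
Title: Cytoplasmic Incompatibility as a Confounder of Intersexual Fitness
    Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how unidirectional cytoplasmic
    incompatibility (CI) caused by maternally transmitted endosymbionts
    such as Wolbachia can mimic intralocus sexual conflict. Provides a
    Monte-Carlo simulator of genotype-level male and female fitness under
    configurable CI scenarios, the intersexual genetic correlation (r_mf)
    statistics used to diagnose sexual conflict (Pearson correlation with
    t-based significance, slope comparison between regressions,
    contingency chi-square and exact binomial sign tests), an isofemale
    line analysis pipeline (Z-standardization by sex and block, line
    means, correlation of line means, CI-line exclusion with
    re-standardization, sex-by-line interaction test), and a synthetic
    isoline data generator with a tunable true intersexual correlation
    and optional CI-affected lines, including a "cured" mode.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
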