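Package: dpirank
Title: Bayesian Indirect Comparison of Dry Powder Inhaler Usability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the short-form Global Usability Score (S-GUS)
    questionnaire for dry powder inhalers, merges all pairwise device
    comparisons from an incomplete-block usability study with a Bayesian
    hierarchical random-effects indirect-comparison model (Gibbs sampler
    with conjugate location updates and truncated variance conditionals),
    and summarizes the posterior as absolute mean differences with
    credible intervals, SUCRA treatment rankings, usability
    classifications, and an I-squared heterogeneity decomposition.
    Includes a synthetic-cohort generator reproducing the two-group
    incomplete-block design, baseline-table statistics (exact Fisher and
    Wilcoxon tests), and a power-based sample-size algorithm.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    stats,
    jsonlite,
    yaml,
    readr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
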