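Package: coldstress
Title: Cold-Stress Grading for Winter-Reared Suckling Calves by AHP and
    Fuzzy Comprehensive Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grades cold stress in suckling calves on a five-level scale
    (none, mild, moderate, severe, extreme) by combining the analytic
    hierarchy process (pairwise judgment matrices, column-normalization
    weights, consistency ratios) with fuzzy comprehensive evaluation
    (membership matrices composed with indicator weights and classified
    by the maximum-membership principle). Also provides environmental
    cold-stress indices (temperature-humidity index, wind-chill
    temperature), tie-corrected Kendall rank association, two-group
    summary tables in the animal-science single-SEM convention, PLS-DA
    with variable-importance-in-projection scores for differential
    metabolite screening, and a seeded generator for synthetic winter
    calf cohorts and two-group metabolomes so the whole pipeline is
    testable without access to farm data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
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
    jsonlite,
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
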