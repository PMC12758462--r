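Package: atlascpet
Title: Centile-Based Severity Classification of Exertional Symptoms During
    Incremental Exercise Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies the whole-test trajectory of exertional symptom
    ratings (Borg CR10 dyspnea and leg effort versus cycle-ergometer work
    rate) recorded during incremental cardiopulmonary exercise testing.
    Trajectories are scored against sex- and age-adjusted reference centile
    curves with a reciprocal exponential loss, inter-centile range scores are
    normalized into probabilities, and the most representative range is
    selected by a generalized binary search and mapped to a four-level
    severity scale. Also provides cohort-level comparisons against
    conventional peak-score classification (cross-tabulations, McNemar's
    test, chi-squared discrimination by patient group), a synthetic-data
    generator for reference tables and ground-truth-labelled cohorts, file
    readers and writers for stage data and centile tables, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
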