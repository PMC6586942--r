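Package: pyroage
Title: Evaluation of Blood-Based DNA Methylation Age Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating pyrosequencing-based DNA methylation age
    prediction models on blood cohorts. Encodes six published epigenetic
    clocks (Bekaert, Park, Thong, Weidner and Zbiec-Piekarska 1 and 2) over
    a panel of 52 CpG sites in 11 genes, reads and validates percent
    methylation cohort tables, computes prediction-accuracy statistics
    (Pearson r, mean absolute deviation, standard error of the estimate,
    percentage of correct predictions) stratified by gender and age group,
    assesses pyrosequencing assays against DNA methylation standards to
    detect PCR amplification bias, analyses duplicate-measurement averaging,
    and simulates synthetic cohorts with a prescribed age-correlation
    structure for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
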