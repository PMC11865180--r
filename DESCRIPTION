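Package: ensembleYN
Title: Analysis of Yes/No Ensemble-Perception Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating, and analysing Yes/No
    recognition experiments that probe ensemble perception of orientation
    and colour. Generates trial sequences for four experiment designs and
    simulates binary responses from parameterised averaging or similarity
    observers; classifies probes by ordinal distance from the display mean
    or from the nearest presented item; computes the similarity-hypothesis
    point prediction for the mean probe; fits three-parameter log-logistic
    psychometric functions under both classificatory schemes and compares
    them by BIC; provides paired t-tests with Cohen's d and JZS Bayes
    factors, one-way and factorial repeated-measures ANOVAs with Tukey
    post hocs; and runs a bootstrap model-selection power simulation.
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
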