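Package: ventrl
Title: Offline Reinforcement Learning for Mechanical Ventilation Settings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns and evaluates dynamically optimized mechanical-ventilation
    policies (tidal volume, PEEP, FiO2) from ICU patient trajectories binned in
    4-hour steps. Implements the full offline pipeline: cohort reading and
    validation, ventilation-event definition, sample-and-hold and kNN/SVD
    imputation, Tukey outlier filtering, k-means patient-state discretization
    with BIC/AIC model selection, a 343-action ventilator-setting grid indexed
    by ideal body weight, tabular Markov-decision-process estimation with
    terminal survival/death rewards, value iteration and sample-based
    Q-learning, weighted-importance-sampling off-policy evaluation with
    bootstrap confidence bounds and ensemble model selection, policy analyses
    (action-frequency deltas, action-change dynamics, out-of-bag feature
    importance, return-vs-mortality curves), and a synthetic ICU cohort
    generator with known ground truth for end-to-end validation.
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
    Matrix,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    arrow,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
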