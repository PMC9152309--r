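Package: habitcast
Title: Habit Dynamics and Next-Day Behavior Forecasting for Digital
    Health Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes latent habit strength and memory accessibility from
    daily behavior logs via bounded gain/decay recurrences, builds
    competing feature sets (weekly self-report surveys, past behavior
    rates, discounted behavior rates, and the theory-derived states) for
    one-step-ahead prediction of next-day non-adherence with logistic
    regression, and compares the models with participant-grouped nested
    cross-validation, random/grid hyperparameter search on inner-loop
    AUC, a full classification metrics battery, and paired McNemar
    tests. Includes a synthetic-study generator emulating toothbrushing
    intervention designs, episode-timestamp preprocessing into day-level
    outcomes, CSV readers/writers, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
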