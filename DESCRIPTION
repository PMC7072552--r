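Package: biphasr
Title: Biphasic Dose-Response Modeling, Screen Classification, and Drug
    Combination Synergy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits cell-viability dose-response curves with three nested
    models (single-target monophasic, modified Hill, and two-site biphasic),
    separating target-specific inhibition (F1, Kd1) from off-target
    toxicity (F2, Kd2) by RMSE minimization with deterministic
    multi-start bounded optimization. Classifies screening responses into
    low-viability, no-inhibition, monophasic, and biphasic categories,
    normalizes raw viability readings against controls, and quantifies
    1:1 drug-combination synergy through ICx estimation and the dose
    reduction index. Includes seeded synthetic data generators so every
    analysis step is testable without external downloads.
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
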