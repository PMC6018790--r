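Package: bpgadose
Title: Warfarin Maintenance Dose Prediction with a Genetic-Algorithm-Initialised Back-Propagation Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts individual warfarin maintenance dose after heart valve
    replacement with a three-layer back-propagation neural network whose
    initial weights and thresholds are searched by a real-coded genetic
    algorithm (roulette selection, single-point crossover, single-gene
    mutation, elitism). Includes ANCOVA partial eta-squared variable
    screening with mandatory-variable enrollment, centre-based external and
    3:1 internal validation splits, accuracy metrics (MAE, RMSE, ideal
    predicted percentage with a 20% band, dose-subgroup breakdowns), and a
    seeded multi-centre synthetic cohort generator so the whole pipeline is
    reproducible without access to registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
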