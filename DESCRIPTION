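Package: neurochair
Title: Simulation of a Brain-Actuated Smart Wheelchair Control Stack
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale, fully simulated re-implementation of a hybrid
    brain-computer-interface wheelchair control stack. Provides seeded
    generators for oddball P300 EEG and jaw-clench EMG signals; a P300
    decoding pipeline (causal band-pass filtering, 800 ms epoching,
    stepwise linear discriminant analysis, candidate-restricted trial
    classification); a windowed-variance EMG validation-command detector
    with FIFO pattern matching; simulated depth-camera sensing with
    point-cloud target localization and PCA orientation estimation; a
    rule-based target-solution planner with a shared-control state
    machine; and a 2D omnidirectional wheelchair simulator with grid
    path planning, closed-loop session replay of scenario task lists,
    and the associated performance metrics.
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
    igraph,
    jsonlite,
    purrr,
    rlang,
    signal,
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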