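Package: spindlr
Title: Sleep Spindle Detection, Thalamic Calcium Signal Analysis and
    Closed-Loop Stimulation Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing murine polysomnography and fiber photometry
    recordings of the somatosensory thalamus. Implements a three-threshold
    sigma-band (9-16 Hz) sleep spindle detector with eight per-event
    characteristics, isosbestic-referenced delta-F/F photometry preprocessing,
    EMG movement labelling, event-triggered averaging and cross-correlograms,
    epoch-level calcium feature extraction with leave-one-subject-out decoding,
    simulation of state-triggered closed-loop optogenetic stimulation
    protocols, go/no-go behavioural scoring (d-prime, bias, disengagement),
    and exact small-sample Mann-Whitney and Wilcoxon signed-rank tests by
    enumeration. Includes a seeded synthetic session generator (hypnogram,
    EEG with embedded spindles, EMG, two-channel photometry) with ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    glmnet,
    generics,
    jsonlite,
    pracma,
    pROC,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
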