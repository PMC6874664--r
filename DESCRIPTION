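Package: pacAtlas
Title: Normative Atlas Z-Scoring of Phase-Amplitude Coupling in
    Intracranial EEG
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how far the slow-wave/high-frequency-activity
    phase-amplitude coupling of an intracranial electrode deviates from an
    anatomically matched non-epileptic normative mean. Computes the
    mean-vector-length modulation index (MI) from slow-wave-sleep epochs on a
    common average reference, builds a surface-based normative atlas of MI
    from the k closest non-epileptic recording sites at each cortical mesh
    vertex, derives per-electrode MI z-scores and per-patient summary scores,
    and provides the downstream statistics used to characterise seizure-onset
    zones and classify postoperative seizure outcome: Wilcoxon signed-rank
    tests on paired medians, multivariate logistic regression with odds
    ratios and Nagelkerke R-squared, ROC/AUC analysis with fixed-sensitivity
    operating points, leave-one-out cross-validation, and sensitivity
    analyses over the atlas neighbourhood size. A synthetic-data module
    generates coupled signals, electrode layouts on a cortical mesh, and
    surgical cohorts with known ground truth so that every stage of the
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
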