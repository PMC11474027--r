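Package: cinephys
Title: Analysis of Optogenetically Identified Striatal Cholinergic
    Interneurons and Dopamine Photometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for striatal cholinergic interneuron (CIN)
    electrophysiology and fiber-photometry dopamine recordings in a
    probabilistic two-choice (bandit) task. Provides optogenetic-tagging
    classification of light-responsive units, tonic-firing and waveform
    metrics, slow-wave-sleep detection from ECoG band-power ratios,
    peri-event time histograms with shuffle-test significance and
    response-onset timing, time-division-multiplexed photometry
    demultiplexing and control-channel dF/F, a Bayesian beta-distribution
    trial-value model with reward-prediction-error regressions, and a
    seeded synthetic-session generator that emulates the task and the
    recorded signals for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
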