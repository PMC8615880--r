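Package: plvnet
Title: Resting-State Phase-Locking Connectivity, Connectome-Based
    Prediction and Nodal Graph Metrics for EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for predicting task-derived behavioral and neural
    indexes from resting-state EEG functional connectivity. Computes
    phase-locking-value (PLV) adjacency matrices from epoched,
    parcellated signals in canonical frequency bands; predicts scalar
    subject-level indexes from network-restricted edge features with
    leave-one-subject-out linear support-vector regression; expresses
    prediction accuracy as a Bayesian correlation with a stretched beta
    prior, including one-sided tests, credible intervals and prior-width
    robustness curves; and characterizes nodes of thresholded weighted
    graphs (degree, strength, weighted clustering, local efficiency)
    with small-world-controlled proportional thresholding and
    degree-preserving rewiring null models. Includes seeded synthetic
    generators for coupled oscillatory epochs, cohort connectivity with
    planted edge effects, and variable-foreperiod reaction-time task
    schedules, so the full pipeline runs end-to-end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    igraph,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
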