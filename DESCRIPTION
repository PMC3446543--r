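Package: recalldyn
Title: Valence-Conditioned Free Recall Dynamics with Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing the dynamics of emotional free recall in
    two-arm, two-timepoint behavioural trials. Computes pooled,
    valence-conditioned recall-dynamics statistics (probability of first
    recall, probability of staying within a valence category, and the
    per-recall stopping hazard), together with per-valence recall
    percentages, and tests group-by-time effects with permutation analogues
    of ANOVA. Includes a constrained affective stimulus-list builder driven
    by word norms, a recall-sequence scorer (targets, buffers, intrusions,
    repetitions), a category-level Markov simulator of recall with item
    depletion for generating synthetic trials, and an end-to-end analysis
    pipeline with calibration utilities.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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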