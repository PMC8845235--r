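Package: icudtr
Title: Dynamic Drug-Prescription Strategies for ICU Cohorts via
    Supervised Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns and evaluates dynamic daily drug-prescription
    strategies for intensive-care patients from offline trajectory data.
    Implements an offline actor-critic learner (deterministic-policy-
    gradient critic with a supervised cross-entropy anchor blended by a
    trade-off weight), windowed state tracking with a diagnosis embedding
    branch, comparison learners (pure supervised, pure reinforcement,
    outcome-weighted direct policy optimization, dual-branch classifier,
    feature-restricted variants), ICU time-series preprocessing (daily
    binning, composite vitals, quantile outlier capping, log transform,
    z-normalization, k-nearest-neighbour imputation, frequency-ranked
    diagnosis encoding), off-policy evaluation by bootstrapped
    return-quantile mortality binning (state-wise and trajectory-wise),
    Jaccard and treatment-difference policy similarity, random-forest
    feature-importance comparison of clinician and learned policies, and
    a synthetic ICU cohort generator with a known behaviour policy and
    outcome model that supports ground-truth policy evaluation by
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
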