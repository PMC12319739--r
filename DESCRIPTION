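Package: temporalmem
Title: Temporal Distortion Metrics and Activation Pattern Similarity for
    Episodic Memory Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for timeline-based episodic memory experiments
    in which participants reconstruct the timing and order of objects within
    episodes and of episodes within runs. Provides a translation/scaling/
    pattern decomposition of timeline responses (1-D Procrustes-style
    alignment), item-level and order scores, shuffle-null testing of measure
    distributions with a 2-Wasserstein bootstrap test and generalized Pareto
    tail refinement, mixed-model inference with AIC-guided term selection and
    quasi-Bayesian causal mediation, first-level event GLMs with a canonical
    double-gamma HRF and DVARS scrubbing, and a searchlight representational
    similarity analysis with multivariate noise normalization and sign-flip
    cluster-mass group inference. Includes synthetic-data generators for
    experiment schedules, distorted timeline responses, and BOLD series with
    planted pattern-integration and pattern-differentiation effects so the
    full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    MASS,
    pROC,
    igraph,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
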