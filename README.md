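# temporalmem

Analysis pipeline for timeline-based episodic memory experiments: how do
people distort time when they remember a sequence of events, and how do
those distortions relate to order memory and to fMRI activation-pattern
geometry?

The experimental paradigm the package targets presents "episodes" — a green
start screen, five objects at irregular times, a red end screen — and later
asks participants to drag each object back onto an empty timeline, and each
episode back onto a run-level timeline. The package provides:

* **Temporal decomposition** of a timeline response into translation
  (centroid misplacement, seconds), scaling (global compression `< 1` /
  expansion `> 1` of recalled intervals, via a 1-D Procrustes-style
  translation + least-squares scale alignment), and a temporal pattern
  score (negated sum of squared residuals to the closest true positions
  after alignment), plus item-level translation/local-scaling and rank-based
  order scores, within episodes and between episodes (including windowed
  run-level variants).
* **Shuffle-null testing**: correctly-labeled vs shuffled score
  distributions per measure, compared with an empirical 2-Wasserstein
  two-sample test (pooled bootstrap null, generalized-Pareto tail
  refinement), ROC/AUC with Youden cutpoints, and Benjamini–Hochberg FDR.
* **Mixed-model inference**: random-intercept linear mixed models (ML),
  forward AIC term selection with optional quadratic terms, VIF
  collinearity checks, quasi-Bayesian causal mediation (ACME/ADE with
  percentile intervals), and Spearman correlation matrices over participant
  means.
* **First-level GLM**: canonical double-gamma HRF, the object-level design
  (245 regressors for the full experiment) and episode-level design
  (241 regressors), DVARS motion scrubbing, per-voxel OLS.
* **Searchlight RSA**: 10-voxel searchlights within a 10 mm radius,
  multivariate noise normalization (shrinkage covariance, inverse square
  root), Mahalanobis RDMs, Spearman model correlations with a temporal
  proximity partial covariate, 6 mm smoothing, and group-level sign-flip
  cluster-mass inference.
* **Synthetic data generators** for all of it: experiment schedules,
  distorted timeline responses with known parameters, and BOLD series with
  planted pattern-integration and pattern-differentiation effects — so the
  whole pipeline is testable end to end without any data download.

## Worked example

```r
library(temporalmem)

# a participant who compresses time by 20%, drifts +0.4 s, and jitters
sch  <- generate_schedule(experiment_design(rng_seed = 1))
pm   <- participant_model(global_scaling_bias = 0.8, translation_bias = 0.4,
                          pattern_noise_sd = 0.3, rng_seed = 2)
resp <- simulate_responses(sch, pm)
mt   <- build_measure_table(sch, resp)
round(colMeans(mt[, c("translation_p1", "scaling_p1", "pattern_p1", "order_o1")]), 3)
#> translation_p1     scaling_p1     pattern_p1       order_o1
#>          0.406          0.800         -0.451          0.025
```

The decomposition recovers the planted distortions: the mean translation is
the planted +0.4 s drift, the mean scaling is the planted 0.8 compression
factor, the pattern score is mildly negative because of the 0.3 s placement
noise, and order errors are rare (2.5% mean rank deviation) because the
noise rarely reorders items.

A single decomposition is just as direct:

```r
decompose_pattern(true_times    = c(1.0, 2.3, 4.1, 7.0, 10.5),
                  recalled_times = c(2.0, 3.1, 4.6, 7.2, 9.9))
#> tm_decomposition: translation 0.380 s, scaling 0.838, pattern score -0.0432
```

This response drifted +0.38 s toward the episode end and compressed the
object pattern to 84% of its true spread (`scaling_compr = 0.162`,
`scaling_exp = 0`); the small residual pattern error is what translation
and scaling cannot absorb.

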