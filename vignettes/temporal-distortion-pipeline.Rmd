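---
title: "Temporal distortions in episodic memory: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal distortions in episodic memory: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temporalmem)
```

# The scientific problem

In timeline-based episodic memory experiments, participants watch short
"episodes" — here, a green start screen, five objects at irregular times, and
a red end screen — and later reconstruct when each object appeared by
dragging it onto an empty timeline. The same reconstruction is done at a
coarser scale for the sixteen episodes of a run. Human temporal memory is
systematically distorted: whole patterns drift (translation), stretch or
shrink (scaling), and individual items jitter or trade places (pattern and
order errors). This package separates those distortions, tests whether each
component is encoded at all, models how they relate to one another, and links
them to fMRI activation-pattern geometry (integration within episodes,
differentiation between episodes).

# The temporal decomposition

Given true times $t_1 < \dots < t_n$ and recalled times $r_1, \dots, r_n$
matched by item identity, `decompose_pattern()` proceeds in three steps:

1. **Translation.** The recalled pattern is shifted so its centroid matches
   the true centroid — the RMSD-optimal 1-D rigid alignment. The reported
   translation is the inverse of the applied shift,
   $\bar r - \bar t$, i.e. how far the participant misplaced the pattern
   relative to the timeline boundaries.
2. **Scaling.** A least-squares scale $s^\ast =
   \sum \tilde t_i \tilde r_i / \sum \tilde r_i^2$ (tildes denote centered
   values) maps the centered recalled pattern onto the true one. The
   reported scaling is $1/s^\ast$: values below 1 mean the recalled pattern
   is tighter than the truth (compression in memory), above 1 expansion.
   Compression and expansion magnitudes are $\max(0, 1-S)$ and
   $\max(0, S-1)$, so exactly one of them is nonzero.
3. **Pattern score.** After translation and scaling, each aligned recalled
   position is compared against the *closest* true position (ties toward the
   earlier one); the squared residuals are summed and negated. 0 is a
   perfect relative pattern, more negative is worse.

Because centroid alignment followed by least-squares scaling on centered
data is exactly the ordinary regression of true on recalled times, the
sequential procedure attains the joint optimum; the test suite verifies this
against a grid-search oracle over (shift, scale) at $10^{-4}$ resolution.

Two degenerate inputs are flagged rather than scored: a recalled pattern
with no spread (all items on one point), and a fitted scale $s^\ast \le 0$
(a fully reversed pattern). Both return `scaling = NA` with residuals
computed at scale 1 and `degenerate = TRUE`.

Item-level measures complement the pattern-level ones: the absolute
deviation of each placed time, and the ratio of the smallest gap to the
item's temporal neighbors in the recalled versus the true pattern (local
compression/expansion). Order scores are absolute rank deviations, ranks
taken by sorting placed times; a full reversal of five items scores
$(4+2+0+2+4)/5 = 2.4$.

# The synthetic-data generator

`generate_schedule()` reproduces the experimental design: 3 runs x 16
episodes x 5 objects, 0.6 s stimuli and boundary screens, and six
inter-stimulus gaps per episode, three drawn uniformly from 0.1–2.0 s and
three from 2.1–3.5 s, with the assignment of ranges to gap positions a
uniformly random permutation. Under these ranges the expected stimulus
period is $7 \times 0.6 + 3 \times 1.05 + 3 \times 2.8 = 15.75$ s, which the
suite checks empirically. Each episode cycle continues with cross-fixation
(10 s), an odd–even task (10 s), the timeline test (modeled as a 10 s
planning phase plus a 40.5 s execution phase, so a typical test lasts about
50 s), and a closing odd–even task that first-level
models leave unmodeled as an implicit baseline.

`simulate_responses()` distorts the true times with a participant model:
centroid-anchored scaling (optionally jittered per episode), additive
translation, Gaussian placement noise, and adjacent-item swaps applied to
the placed times so order and timing errors stay coupled as in a
drag-and-drop interface. Placements are clipped to the timeline bounds —
the test interface cannot place an item outside the episode. Clipping
censors strongly expanded patterns, so noiseless recovery of a planted
scaling bias is exact for the *median* episode rather than for every
episode; the recovery checks use the median for that reason. Under
placement noise the least-squares scaling estimate carries a small
attenuation-type bias of order $\sigma^2 / SS_t$ (about 0.004 at the
generator's default noise); it does not vanish with more episodes but is an
order of magnitude below the 0.02 recovery tolerance used in the checks.

Two couplings make planted behavioral structure available to the model
stage: across participants, the scaling bias, placement noise, and swap
probability rise together; and within participants,
`noise_scaling_exponent` makes episodes that happen to be compressed more
precisely encoded (noise SD multiplied by $S^{2}$ by default in
`simulate_cohort()`). The second, trial-level coupling is what the
random-intercept mixed models and the mediation analysis detect; a purely
participant-level coupling would be absorbed by the random intercepts.

What the generator does *not* emulate: realistic forgetting dynamics,
response-time structure, strategic placement (e.g. anchoring on boundaries),
or heavy-tailed placement errors. Passing tests demonstrate that the
estimators recover what was planted, not that real data behave this way.

# Null distributions and the separation test

For each memory measure, the correctly-labeled distribution of
per-participant average scores is compared with a shuffled distribution:
timeline responses rescored against the 47 other episodes' true patterns
(expressed relative to each episode's green screen), random rank sequences
for the order measures (5000 repeats), random 5-item draws from the full
recognition pool, and random episode groupings for association. Separation
is tested with the empirical 2-Wasserstein distance
$W_2^2 = \int_0^1 (F_a^{-1}(p) - F_b^{-1}(p))^2\,dp$, computed exactly by
quantile coupling. The null is built by resampling both groups from the
pooled sample (5000 bootstrap draws by default); when the observed distance
exceeds the 90th null percentile, the tail p-value is refined by a
maximum-likelihood generalized Pareto fit to the null exceedances, falling
back to the empirical p-value (with a flag) if the fit fails. ROC curves,
AUC, and the Youden-index cutpoint come from pROC; the Youden criterion is
a package choice where the underlying procedure is ambiguous. The suite
verifies the type-I error of the whole construction at $\alpha = 0.05$ over
200 null simulations of 30 participants each (400 bootstraps per test to
keep the run short).

# Mixed models, selection, and mediation

All trial-level inference uses Gaussian linear mixed models with a random
intercept per participant, estimated by maximum likelihood so AIC values
are comparable across fixed-effect structures; p-values are Wald z tests.
Term selection is forward-only: starting from the intercept-only model, the
candidate (or its centered quadratic, where offered) with the largest AIC
improvement enters until none improves; the path is logged. Forward-only
search is a deliberate simplification of order-heuristic term builders —
the selection direction is not identifiable from the procedure description
we follow, and forward selection is reproducible and cheap. Collinearity is
monitored with classical VIFs computed from the inverse predictor
correlation matrix. Missing rows are dropped listwise per model with a
mandatory count in the fit object.

Causal mediation combines the mediator model (mediator ~ treatment) and
outcome model (outcome ~ treatment + mediator), both with random
intercepts, via quasi-Bayesian Monte Carlo: coefficients are drawn from
each fit's asymptotic normal, the indirect effect is the product of the
treatment-to-mediator and mediator-to-outcome draws, and percentile 95%
intervals are reported (5000 draws by default). The mediation is only
*assessed* when both path coefficients are significant at 0.05; the
estimates are returned either way, flagged. The suite checks 95% CI
coverage of a planted indirect effect across 100 simulated cohorts of 40
participants (2000 draws per fit there — the draw count affects only the
Monte Carlo error of the interval endpoints).

# First-level GLM and searchlight RSA

Event models use the SPM-convention double-gamma HRF (peak 6 s, undershoot
16 s, ratio 1/6, 32 s support, unit peak). Model one has one regressor per
object event plus cross-fixation, post-fixation odd–even, timeline planning,
and timeline execution regressors and an intercept — 245 columns for the
full experiment; model two has one regressor per episode for each of five
periods plus an intercept — 241 columns. No drift or high-pass regressors
are added, a fidelity choice matching the modeled regressor set; motion
artifacts are handled by DVARS spike regressors instead (box-plot fence:
75th percentile + 1.5 IQR). The GLM is ordinary least squares per voxel;
temporal autocorrelation correction of the GLM itself is intentionally out
of scope, and the simulator's AR(1) noise is mild.

Searchlights are the 10 nearest in-mask voxels within 10 mm of each center
(ties at the cutoff broken by lexicographic grid order; centers with fewer
than 10 eligible neighbors are skipped with a report). Within each
searchlight, the GLM residual covariance is shrunk toward its diagonal with
the analytic optimal-shrinkage intensity (shrinkage is forced to at least
0.1 when there are fewer residual frames than voxels) and the patterns are
multiplied by its inverse square root, making squared Euclidean distances
Mahalanobis distances. Observed dissimilarities are correlated with a model
vector by Spearman's rho — partial rank correlation when a temporal
proximity covariate is supplied. The within-episode model assigns every
same-episode object pair the episode's signed contrast
(expansion − compression), predicting larger dissimilarity for expanded
episodes; a binary encoding is available. The between-episode model uses
absolute differences of a per-episode scaling variable. Correlation maps
are Fisher-z transformed, smoothed with a mask-renormalized 6 mm FWHM
Gaussian at the single-subject level, and tested at the group level with
one-sample t-tests, cluster formation at one-sided p = 0.001, cluster mass
statistics, and a max-statistic sign-flip null (all $2^n$ flips for up to
12 subjects).

The temporal-proximity covariate matters beyond its scientific motivation:
with single-event regressors only ~2 s apart under a 2.57 s TR, beta
estimates of nearby events are strongly correlated, and the estimation-error
geometry alone imprints structure on the distance ranks. Partialling the
pair lag removes the bulk of it; the simulator's event amplitudes are set
well above the residual estimation noise so that what remains is negligible
relative to planted effects (verified by the null false-positive runs).

# Planted-effect recovery and problem sizes

`simulate_bold()` plants both neural effects inside a central spherical
signal region: object patterns are mixtures
$w_k E_k + (1-w_k) U_j$ of a shared episode pattern and object-unique
patterns with $w_k$ increasing as the episode's *measured* scaling
decreases (integration), and episode patterns are displaced along a common
direction in proportion to the episode's measured between-episode expansion
(differentiation), so episode-pair distances track
$|\mathrm{exp}_i - \mathrm{exp}_j|$ exactly as the model RDM assumes.
Outside the region, event amplitudes are unstructured.

The recovery suite runs `simulate_rsa_study()`: 12 subjects, each with
their own one-run 16-episode schedule (inter-episode periods shortened to
keep a run near 200 frames), a 16x16x16 voxel grid at 3 mm, event
amplitude 12 against AR(1) noise of SD 0.25. The amplitude/noise ratio was
fixed by a pilot signal-to-noise calculation so that a strength-3
integration effect or strength-2 differentiation effect is comfortably
detectable with 12 subjects, while zero-strength data stay null; five
datasets per planted condition and ten null dataset-analyses are used in
the checks (power $\ge$ 80%, false positives $\le$ 10%). These sizes are
the package's chosen desk-scale study conditions; a real study would use
the full three-run design and a brain-shaped mask.

# Numerical choices and limitations

* Closest-position ties in the pattern score go to the earlier true
  position; correspondence for the translation/scale fit is by item
  identity (drag-and-drop provides identity), residuals only use
  closest-position matching.
* Signed translation is kept internally; models may use its absolute value
  (`translation_p1_abs`), since the sign convention of the original measure
  is ambiguous.
* The W2 bootstrap uses pooled resampling with replacement; the GPD tail
  fit requires at least 10 exceedances and otherwise falls back,
  flagged.
* Recognition scoring counts non-lures in both the labeled and the
  shuffled draws, keeping the two distributions on one scale.
* The between-run shuffled distributions for the run-level timing measures
  compare each run's placements against the other runs' true patterns (two
  comparisons per run) — the within-episode case pins down 47 comparisons
  per episode, the run-level analogue is the package's extension.
* Cluster inference assumes exchangeable, symmetrically distributed subject
  maps under the null; subject-specific schedules make the map-level
  nuisance shift independent across subjects.
* `fit_glm()` is plain OLS; prewhitening happens in the RSA stage, not in
  the GLM.
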