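---
title: "Testing whether ipsilateral motor recruitment is compensatory: models and methods"
author: "haroldmvb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing whether ipsilateral motor recruitment is compensatory: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haroldmvb)
```

## The scientific question

Older adults commonly show more activity in the motor cortex *ipsilateral*
to the moving hand than younger adults do, while contralateral activity
declines — the HAROLD pattern (hemispheric asymmetry reduction in older
adults). Two families of explanation compete:

* **Compensation**: the extra ipsilateral activity does computational work,
  so it should (a) relate to better behavioural performance, increasingly so
  at older ages, and (b) carry *unique* task information over and above the
  contralateral hemisphere.
* **Inefficiency / dedifferentiation**: the extra activity is nonspecific;
  it carries no unique information and has no behavioural benefit.

Crucially, mean activation and information can dissociate: a region's mean
response can rise with age while the information its multivoxel pattern
carries about the task stays flat or falls. `haroldmvb` implements the full
inference chain that separates these readings — a first-level fMRI GLM,
region-of-interest (ROI) tools, a multivariate Bayes (MVB) decoder with a
log-evidence "boost" model comparison, a support-vector-machine finger
decoder, and lifespan statistics — together with a synthetic cohort
generator whose ground truth can embed or withhold true compensation, so the
whole chain is testable end to end without any imaging download.

## The synthetic cohort generator

`cohort_spec()` fixes every generating parameter; `simulate_cohort()` is a
pure function of the spec and its seed. The generator emulates two
event-related designs at TR = 1.97 s:

* a *sensorimotor* run — 120 bimodal audio/visual trials plus 8 unimodal
  catch trials over 261 scans, with stimulus onset asynchronies between 2
  and 26 s drawn from a truncated geometric mixture over 2 s null slots
  (sparse event-related timing; the published schedule-optimisation
  algorithm is not public, and the generator makes no claim to match it);
* a *free-selection* run — 240 finger presses in 12 blocks of 20 separated
  by 4.2 s or 6.2 s gaps, 120 trials with a specified finger (30 per
  finger) and 120 free-choice trials among three cued fingers, with no four
  consecutive trials of the same condition type.

Each participant's BOLD data are condition amplitudes times a declining
voxel profile (plus finger-specific pattern components in the
free-selection design), convolved with the canonical haemodynamic response,
on a baseline of 100, with slow cosine drift below 1/128 Hz and AR(1) noise
(default coefficient 0.2, innovation SD 1). The contralateral region is
simulated with twice the nominal voxel count so voxel-count-matched control
analyses can extend it by next-ranked voxels.

**Age laws.** Mean amplitudes (arbitrary units of the 100-unit baseline)
follow quadratic lifespan laws centred at 50 years: contralateral
`1.0 − 0.006·(age − 50)` (declining), ipsilateral
`0.45 + 0.008·(age − 50) − 0.00012·(age − 50)²` (rising, flattening around
the early 80s), each with a between-subject SD of 0.12. Reaction times are
normal per trial with participant-level mean `320 + 1.0·(age − 50)` ms and
SD `55 + 0.8·(age − 50)` ms, plus participant-level variability (SD 25 and
10 ms). These magnitudes were chosen once as plausible for a lifespan
button-press cohort: amplitudes of order 1% of baseline, reaction-time
means in the low hundreds of milliseconds with worsening variability in
old age.

**Scenarios.** All three scenarios share the amplitude laws — the
univariate HAROLD pattern is present by construction in every one — and
differ only in what the rising ipsilateral amplitude *means*:

* `haroldnull`: ipsilateral noise scales with ipsilateral amplitude, so the
  signal-to-noise ratio (and hence decodable information) is age-flat.
  This is the "nonspecific hyperactivation" world.
* `compensation`: noise does not scale, so ipsilateral information rises
  with amplitude; additionally reaction-time variability is coupled
  negatively to ipsilateral activation with a coefficient that grows with
  age (interaction coefficient −8 ms per SD×SD, i.e. half the magnitude of
  the age main effect on RT variability, plus a −4 ms main effect).
* `dedifferentiation`: ipsilateral noise grows faster than amplitude, so
  information falls with age.

What the generator does **not** emulate: head motion, slice-timing and
registration error, multi-run sessions, non-linear haemodynamics, spatial
noise correlations, and real anatomical geometry. Tests passing on this
generator therefore validate the *statistical machinery* — estimator
calibration, decoder behaviour, threshold semantics — not robustness to
those acquisition artifacts.

## First-level GLM

`build_design_matrix()` convolves condition onsets with the canonical
double-gamma haemodynamic response (delays 6 s / 16 s, unit dispersions,
amplitude ratio 6, 32 s kernel, unit peak) and optionally its temporal and
dispersion derivatives; the discrete-cosine high-pass set retains
`floor(2·T/128) + 1` orthonormal columns (periods above 128 s, including
the constant). Data are scaled to a session grand mean of 100, so betas
read as percent signal.

The noise model is AR(1)-plus-white: `V = (1 − m)·I + m·Q(φ)` with `Q(φ)`
the unit-diagonal AR(1) correlation matrix and `m` the autoregressive
variance share. Per-voxel scale is profiled out and `(φ, m)` are found by
direct maximisation of the pooled restricted log-likelihood,
Yule-Walker-initialised. Direct maximisation replaces the textbook
expectation-maximisation loop because the objective is identical while
behaving better on the nearly-white boundary, where the AR coefficient is
weakly identified; initialising at the pooled Yule-Walker moments keeps the
estimate honest there. Pooling is over the analysed voxel set (the ROI
voxels entering a given analysis), which matches how the estimates are
consumed. Model and data are then prewhitened with `V^{-1/2}` and fitted by
ordinary least squares.

Trial-wise patterns for decoding use the least-squares-separate approach
(`lss_betas()`): one model per trial, with the target trial's regressor
plus a single regressor aggregating all other trials, which stabilises
single-trial estimates under rapid designs.

## Regions of interest

`select_roi()` finds the suprathreshold local maximum nearest a world-space
landmark (the hand knob, in the real analysis) and grows a 26-connected
neighbourhood from it, admitting voxels in descending statistic order until
exactly `k = 70` voxels; 26-connectivity region growth is our concretion of
"rank selection around a peak", which does not itself fix a connectivity
rule. `mirror_roi()` flips the sign of the world x coordinate to create
the homotopic ipsilateral mask; combined, the bilateral set holds
70 + 70 = 140 voxels. (Published counts for this combined set appear both
as 138 and as 140 in the source analyses; the package fixes the
self-consistent 140.) A 10 mm Gaussian smoother (`smooth_map()`, separable,
edge-renormalised) exists for ROI definition only — every analysis
downstream of ROI definition uses unsmoothed data. Because the ROI is
selected on an age-averaged map, selection does not bias age tests; the
test suite verifies the false-positive rate of an age test on ROI means
from null data stays at the nominal level.

## Multivariate Bayes decoding

MVB reverses the GLM: a scan-length target variable — the task contrast
applied to the design's task regressors (action versus baseline) — is
predicted from many voxels at once. `prepare_target()` projects the
contrast's null space (the other task columns), the high-pass set and any
confounds out of both target and voxel data, after whitening.

`fit_mvb()` places a sparse spatial prior on the voxel weights: patterns
are individual voxels, with prior variances shared within nested subsets.
The greedy search orders voxels by the magnitude of their regularized
projection onto the target, grows the active subset by doubling (1, 2, 4,
…, capped at 8 steps), adds one variance component per added shell, and at
each step re-estimates all hyperparameters by maximising the free energy.
For this linear-Gaussian model the free energy at the optimum equals the
log marginal likelihood of the target under the scan-space covariance
`σ²I + Σ_j λ_j X_j X_jᵀ`, which the implementation evaluates exactly (in a
reduced space of the voxel matrix's rank, for speed) and climbs by
quasi-Newton ascent with analytic gradients; there is no residual
variational gap to report. We treat the free energy as the standard *lower*
bound on log evidence that the scheme maximises; descriptions of it as an
upper bound exist in the literature but are not implemented literally.
The search stops at the first step that fails to improve the free energy
and returns the best model; the returned step trace is non-decreasing by
construction. Posterior mean weights are zero outside the selected subset;
`weight_spread()` (the population SD of weights over voxels) indexes
distributed multivariate information.

Degenerate noiseless problems make the marginal likelihood unbounded as the
noise variance goes to zero; hyperparameters are bounded (log scale ±25)
and non-finite evaluations are penalised, so the optimiser returns the
best bounded model instead of diverging.

**Reliability filter.** Decoding must be demonstrably possible before a
model comparison is meaningful. `phase_shuffle()` randomises the Fourier
phases of the target (conjugate-symmetrically; amplitude spectrum and mean
preserved), giving a null target with the original autocorrelation. A
participant enters the boost analysis only if the real bilateral model's
free energy exceeds the mean over 20 shuffled fits by more than 3 nats
(strict); the shuffle count is our choice, as is averaging over shuffles
rather than taking a single reference. Both the per-participant criterion
and the group one-tailed t-test of the mean difference against 3 are
computed and reported, since either could serve as the exclusion rule.

**Boost comparison.** Per participant, Δ = F(bilateral) −
F(contralateral-only). Δ > 3 is a `boost`, Δ < −3 a `reduction`, the
closed interval between them `ambiguous`; 3 nats corresponds to a Bayes
factor of e³ ≈ 20.1 > 20, conventionally strong evidence. Because the
bilateral model has twice the voxels, two voxel-count-matched controls
re-run the comparison: halving the bilateral set (a seeded 35 + 35
hemisphere-balanced subsample — the subsampling rule is our choice) with a
fresh reliability filter, and doubling the contralateral set with its
next-ranked reserve voxels (the source of extra voxels is our choice,
by statistic rank).

## MVPA finger decoding

For the free-selection design, `decode_fingers()` trains a multiclass
linear support-vector machine (one-versus-one binary learners, cost 1 —
the implementation's pinned defaults; `e1071`/libsvm) on trial-wise betas
normalized per voxel to [−1, 1], with random fourfold cross-validation and
stratified refolding only when a random draw leaves a class out of a
training fold. Specified and choice trials are pooled by the executed
finger. Balanced accuracy (mean per-class recall, averaged over folds)
handles the class imbalance that free choice produces; four-class chance
is 25%, and participants with bilateral accuracy ≤ 25% are excluded from
the accuracy-boost analysis. Because folds come from a single run,
temporal autocorrelation makes training and test sets non-independent and
can bias absolute accuracies upward; only *differences* between voxel sets
(the bilateral-minus-contralateral accuracy boost) are interpreted.

## Lifespan statistics

All participant-level models use standardized linear age and the
re-standardized square (`age_terms()`). Continuous outcomes are fitted by
Huber M-estimation (tuning constant 1.345, the conventional 95%-efficiency
choice) with a two-tailed Wald F test on the age (or interaction) block
using the Huber sandwich covariance of the M-estimator; per-term tests are
reported only when the block test passes α = 0.05. R² is reported as the
percentage of weighted variance uniquely explained, which can run higher
than its ordinary-least-squares counterpart.

The compensation readouts are: the age × ipsilateral-activation
interaction on reaction-time summaries (`compensation_interaction()`), and
the ipsilateral × contralateral interaction for "walking-stick" partial
compensation (`partial_compensation()`). Boost categories are regressed on
standardized age with a proportional-odds model over
`reduction < ambiguous < boost` (`MASS::polr`), falling back to binary
logistic regression when only two categories occur (flagged in the
output); odds ratios above 1 mean boosts become more likely with age.

Two Bayes factors quantify evidence *for* the null:

* `bf_continuous_null()` compares nested linear models under the
  Zellner-Siow mixture-of-g (Cauchy) prior on standardized effects,
  integrating the marginal likelihood over the mixing variance on a fixed
  log-spaced grid. The default comparison drops the interaction block only,
  keeping main effects in both models.
* `bf_directional_categorical()` fits a Bayesian logistic regression of
  the binary boost outcome on standardized age under Student-t priors (7
  degrees of freedom, mean 0, scale 10 for the intercept and 1 for the
  slope) and reports the prior-to-posterior odds of a *positive* slope —
  with the symmetric prior this is the posterior odds of `slope ≤ 0`
  against `slope > 0`. The posterior is drawn with an adaptive random-walk
  Metropolis sampler (4 chains, 2000 kept draws each after 500 warm-up);
  a split-chain R-hat above 1.1 flags non-convergence in the output rather
  than stopping the analysis.

BF01 bands follow the Jeffreys convention: (1, 3] anecdotal, (3, 10]
substantial, > 10 strong evidence for the null; values below 1 favour the
alternative.

## Orchestration, determinism and problem sizes

`run_experiment()` wires the stages into an experiment-shaped report
(univariate age tables, behavioural interaction tables with BF01 columns,
the boost category table with its ordinal regression and directional BF,
and — for the free-selection design — the MVPA accuracy and boost tables),
recording every derived stage seed, threshold and timing in a manifest; a
stage failure produces a partial bundle with a machine-readable error
entry. Every random step in the package consumes an explicit seed, and
cohorts are bit-identical given `(spec, seed)`.

The test suite and `scripts/acceptance.R` run the expensive calibration
checks at deliberately reduced problem sizes chosen to keep the full-chain
Monte-Carlo loops proportionate while preserving the quantities being
calibrated: participant-level calibration (the interaction false-positive
rate at n = 586 over 400 replicates, power at n = 586 over 100 replicates)
uses the summary-level generator, in which measured region means are true
amplitudes plus Gaussian measurement error (SD 0.1) standing in for GLM
estimation error; imaging-path calibration (the boost odds-ratio coverage,
20 replicates) uses 60 participants, 8 voxels per region, 140 scans and 3
shuffled reference fits. The tiny packaged fixture (12 participants, 16
voxels, 120 scans, reduced trial count) exists for fast end-to-end checks;
`make_fixture("standard")` reproduces the full task geometry
(100 × 70 × 261).

## Numerical choices and edge cases

* Boundary semantics are strict everywhere they matter: Δ exactly 3 is
  `ambiguous`, a reliability margin of exactly 3 is excluded, bilateral
  accuracy of exactly 25% is excluded.
* Constant voxels in MVPA normalization map to 0 with a warning; constant
  activation vectors in the regression models raise rank-deficiency
  errors naming the offending columns.
* The event-schedule samplers repair infeasible draws (shrinking the
  largest gaps; resampling condition sequences on dead ends) and fail
  loudly when a design cannot fit the run.
* Mirroring requires an affine symmetric about the midline; mirrored
  voxels that leave the grid are an error, not a silent drop.

## A worked miniature

```{r example, eval = FALSE}
spec <- cohort_spec(30, seed = 11, scenario = "compensation",
                    n_voxels = 8, n_scans = 140,
                    schedule_args = list(n_bimodal = 60, n_unimodal = 4))
cohort <- simulate_cohort(spec, level = "bold") |> run_univariate()
records <- run_mvb_boost(cohort, shuffles = 3, seed = 12)
ordinal_boost_regress(records[records$included, ])
autoplot(cohort)
plot_boost(records)
```

## Known limitations

* The decoder implements the sparse (voxel-pattern) prior only, and only
  one-dimensional (two-state) target contrasts; smooth and support-vector
  pattern priors are out of scope.
* Absolute MVPA accuracies are biased by within-run cross-validation (see
  above); only between-ROI differences are meaningful.
* The sampler behind the directional Bayes factor is a random-walk
  Metropolis — adequate for the 2-parameter logistic posterior it serves,
  not a general-purpose engine.
* The generator's measurement-error stand-in at summary level is Gaussian
  and homoskedastic, which real GLM estimation error is not.
* Cross-sectional inference only: age effects here are individual
  differences, not longitudinal change.
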