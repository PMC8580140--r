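# haroldmvb

Does the extra ipsilateral motor-cortex activity that older adults show
during hand movements — the HAROLD pattern (hemispheric asymmetry reduction
in older adults) — actually *do* anything? `haroldmvb` is an R package for
neuroimaging statisticians and ageing researchers that implements the full
inference chain for answering that question with multivariate Bayes (MVB)
decoding and lifespan behavioural models, exercised end to end on a
synthetic cohort generator with known ground truth.

## The core idea

Mean activation and task information can dissociate. The package therefore
tests compensation on three fronts:

1. **Behaviour** — robust lifespan regression of reaction-time mean and
   variability on standardized linear and quadratic age, ipsilateral
   activation, and their interaction (Huber M-estimation, sandwich Wald
   tests). Compensation predicts an age × ipsilateral interaction.
2. **Model evidence (MVB)** — a Bayesian decoder predicts the
   action-versus-baseline contrast `t` from voxel data `X` under a sparse
   spatial prior, maximising the free energy `F` (the log marginal
   likelihood of the linear-Gaussian decoder, climbed over nested voxel
   subsets by greedy search). The per-participant **boost**
   `Δ = F_bilateral − F_contralateral` is categorized at ±3 nats
   (`exp(3) ≈ 20.1 > 20`, a strong Bayes factor):
   boost / ambiguous / reduction. Compensation predicts boosts to become
   *more* likely with age (ordinal-regression odds ratio > 1). Participants
   must first beat a phase-shuffled decoding null by > 3 nats; controls
   re-run the comparison with voxel counts equated (halved bilateral or
   doubled contralateral models).
3. **Pattern decoding (MVPA)** — one-vs-one linear SVM decoding of which
   finger was pressed, balanced accuracy over random fourfold
   cross-validation (chance 25%), and the bilateral-minus-contralateral
   accuracy boost regressed on age.

Bayes factors for the null (Zellner–Siow mixture-of-g for continuous
models; a directional posterior-odds BF under Student-t(7) priors for the
categorical boost) quantify evidence *against* compensation, interpreted on
the Jeffreys bands (3–10 substantial, > 10 strong).

The synthetic cohort generator embeds the HAROLD amplitude pattern in every
scenario (ipsilateral mean rising with age with quadratic flattening,
contralateral falling) and varies only what it means: `haroldnull`
(information age-flat), `compensation` (information rises and couples to
behaviour), `dedifferentiation` (information falls).

## Worked example

Simulate a small compensation-scenario cohort, run the imaging path, and
ask whether the evidence boost grows with age:

```r
library(haroldmvb)

spec <- cohort_spec(30, seed = 11, scenario = "compensation",
                    n_voxels = 8, n_scans = 140,
                    schedule_args = list(n_bimodal = 60, n_unimodal = 4))
cohort  <- run_univariate(simulate_cohort(spec, level = "bold"))
records <- run_mvb_boost(cohort, shuffles = 3, seed = 12)
records
#> <boost_records> mode: main, 30 participants (30 included)
#>
#> reduction ambiguous     boost
#>         0        10        20

ordinal_boost_regress(records[records$included, ])
#> <boost_ordfit> binary regression of boost category on age, n = 30
#>   categories: reduction=0, ambiguous=10, boost=20
#> # A tibble: 1 × 8
#>   term  estimate std.error odds.ratio conf.low conf.high statistic p.value
#>   <chr>    <dbl>     <dbl>      <dbl>    <dbl>     <dbl>     <dbl>   <dbl>
#> 1 z_age     1.55     0.558       4.71     1.58      14.1      2.77 0.00553
```

Every participant passed the phase-shuffled reliability filter; no
reductions occurred, so the ordinal model fell back to binary logistic
regression (flagged as `binary`). The odds ratio of 4.71 (> 1) says a
log-evidence boost from adding ipsilateral voxels becomes more likely with
age — the generator's built-in compensation, correctly detected. On a
`haroldnull` cohort the same pipeline yields an odds-ratio confidence
interval covering 1.

`autoplot(cohort)` draws the lifespan amplitude trajectories,
`plot_boost(records)` the per-participant evidence differences against the
±3 nats band, and `tidy()` / `glance()` expose every fitted model as a
tibble.

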