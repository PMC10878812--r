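# dyadsync

Analysis of how moving in synchrony with a partner changes response
inhibition under that partner's observation — for cognitive and social
neuroscientists working with dyadic movement recordings, Go/NoGo
behavioural logs and continuous-wave fNIRS.

The package implements three linked analysis stages plus the synthetic
generators that make each stage verifiable by parameter recovery:

1. **Motor-synchrony manipulation check.** Upper-body pose per video frame
   (7 keypoints: neck, shoulders, elbows, wrists) is summarised by its
   pose matrix *D* (pairwise Euclidean distances). Two poses are compared
   via degree-normalized graph Laplacians: with *D* scaled to unit
   Frobenius norm, the affinity is *W* = max(*D*) − *D* and
   *L* = *I* − Deg<sup>−1/2</sup> *W* Deg<sup>−1/2</sup>; the frame score is

   score = 1 / (1 + *k*‖*L*<sub>a</sub> − *L*<sub>b</sub>‖<sub>F</sub>),  score ∈ (0, 1]

   (1 = identical pose structure; *k* is a packaged sensitivity constant).
   Dyad similarity is the mean over frames after median imputation of
   missing keypoints and Savitzky–Golay smoothing (window 13, order 2).
2. **Go/NoGo behaviour.** Hierarchical Bayesian models (Gibbs sampling):
   reaction times RT ~ 1 + Group×BlockType + (1 + BlockType | participant)
   with lognormal likelihood, commission errors CE ~ 1 + Group +
   (1 | participant) with Poisson likelihood, and the exploratory Poisson
   model linking commission counts to mean RT. Effects are summarised by
   posterior means and 95% highest-posterior-density (HPD) intervals, on
   the model scale and on the response scale (ms; counts per 80 NoGo
   trials). PSIS-LOO model comparison is built in.
3. **fNIRS amplitudes.** Raw two-wavelength intensity → optical density →
   HbO/HbR via the modified Beer–Lambert law (partial pathlength factor
   0.1), downsampling 4.5 → 0.6 Hz, a GLM with 16-s-boxcar ⊗ canonical-HRF
   task regressors, cosine drifts to 0.01 Hz, all short-channel principal
   components, and an AR(1) noise model; channel amplitudes are pooled per
   region of interest by inverse variance. Second level: a multivariate
   (HbO, HbR) hierarchical model with marginal contrasts, the HbO−HbR
   difference statistic with negative-correlation filtering, and a
   brain–behaviour model with per-cell RT and commission-error slopes.

Every stage has a generator (`simulate_task_schedule()`,
`simulate_behaviour()`, `simulate_dyad_motion()`, `simulate_fnirs()`)
producing data with that stage's assumed structure and known ground truth.

## Worked example

```r
library(dyadsync)

# -- movement similarity: a mirror-game dyad vs an observation-task dyad --
sync <- simulate_dyad_motion(motion_params("synchronized", seed = 1))
ctrl <- simulate_dyad_motion(motion_params("control", seed = 1))
glance(dyad_similarity(sync$participant, sync$confederate))
#> # A tibble: 1 x 3
#>    mean     sd n_frames
#>   <dbl>  <dbl>    <int>
#> 1 0.811 0.0722     9000
glance(dyad_similarity(ctrl$participant, ctrl$confederate))
#> # A tibble: 1 x 3
#>    mean     sd n_frames
#>   <dbl>  <dbl>    <int>
#> 1 0.436 0.0831     9000

# -- behaviour: simulate a cohort and fit the RT model ---------------------
sched  <- simulate_task_schedule(seed = 11, n_blocks = 20)
trials <- simulate_behaviour(behaviour_params(n_per_group = 20, seed = 12),
                             sched)
fit <- fit_rt_model(trials, seed = 13)
dplyr::filter(tidy(fit), scale == "ms")
#> # A tibble: 3 x 5
#>   effect          scale estimate hpd_lo hpd_hi
#>   <chr>           <chr>    <dbl>  <dbl>  <dbl>
#> 1 block_effect_ms ms      146.   142.   150.
#> 2 group_effect_ms ms       20.1   14.0   27.0
#> 3 interaction_ms  ms        1.73  -6.05   8.97
```

The similarity means land at the two regime calibration points (mirrored
movement ≈ 0.80, alternating solo movement ≈ 0.43). The RT fit recovers
the generating marginal effects: Go responses ≈ 147 ms slower in Mixed
blocks (inhibition cost) and a ≈ 18–20 ms group difference (Control
faster), with 95% HPD intervals.

The full chain — simulate, score, fit behaviour, run the fNIRS first and
second levels, and render a markdown report — runs from one seeded
configuration:

```r
run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
```

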