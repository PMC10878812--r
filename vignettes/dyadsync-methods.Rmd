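---
title: "Models and methods: dyadic synchrony, Go/NoGo behaviour and fNIRS amplitudes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: dyadic synchrony, Go/NoGo behaviour and fNIRS amplitudes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
pose-similarity score used as a motor-synchrony manipulation check, the
hierarchical Bayesian models for Go/NoGo reaction times and commission
errors, the continuous-wave fNIRS first-level pipeline, and the
second-level inference on HbO/HbR amplitudes and their difference. It also
documents the synthetic-data generators that stand in for the study's
video, behavioural and optical recordings, and every numerical choice a
maintainer might want to revisit.

## The scientific setting

A participant and a confederate either play a mirror game (synchronized
dyads) or take turns moving while the other observes (control dyads), and
the participant then performs a Go/NoGo response-inhibition task under the
confederate's observation: 40 blocks of 12 trials, 20 AllGo blocks (only
Go trials) and 20 Mixed blocks (8 Go, 4 NoGo). Behavioural outcomes are
Go-trial reaction times (RT) and commission errors (CE; button presses on
NoGo trials, at most 80 per participant). Cortical outcomes are evoked
HbO/HbR amplitude estimates over five frontal regions of interest (left
and right inferior frontal gyrus, left/middle/right prefrontal cortex)
from continuous-wave fNIRS at 760 and 850 nm.

Because no raw recordings are available, every stage here is paired with a
generator that produces data with that stage's assumed statistical
structure and known ground truth, so the analysis chain is validated by
parameter recovery rather than by re-reading published estimates.

## Pose similarity

Upper-body pose per person per video frame is seven 2-D keypoints (neck,
shoulders, elbows, wrists) in image coordinates (y grows downward, the
pose-estimation convention). The preprocessing chain is: flag keypoints
with confidence 0 as missing; drop frames in which a person has more than
half their joints missing (imputing an entire pose would fabricate
geometry); replace remaining missing coordinates with that joint's median
over the recording; smooth each trajectory with a Savitzky-Golay filter
(window 13 frames, polynomial order 2 -- at 30 fps a 0.43-s window, which
preserves movement up to quadratic local trends and removes frame-level
estimation jitter). Confidence values are used only to flag missingness;
no confidence weighting is applied, since median imputation is the only
treatment of uncertainty the procedure defines.

Each frame's pose is summarised by its pose matrix `D`: the 7x7 Euclidean
distance matrix between joints, which is invariant to translation,
rotation and reflection of the pose. Two poses are compared through
degree-normalized graph Laplacians: scale `D` to unit Frobenius norm
(removing body size), form the affinity `W = max(D) - D` off-diagonal,
and the symmetric normalized Laplacian
`L = I - Deg^(-1/2) W Deg^(-1/2)`. The score is

    score = 1 / (1 + k * ||L_a - L_b||_F)

which is 1 exactly when the normalized pose matrices coincide, bounded in
(0, 1], symmetric, and invariant to rigid motion and isotropic scaling of
either pose. The sensitivity constant `k` (packaged value 3.9,
`similarity_gain()`) is part of the score's definition here: without it
the Frobenius distance between normalized 7-node Laplacians saturates
around 1, so raw `1/(1+d)` cannot reach the low similarity values
characteristic of independent movement; `k` sets the dynamic range so
that fully mirrored motion and independent motion land at the two
study-level reference means (0.80 and 0.43). `k` was fixed once against
the motion generator and is not a per-run tuning knob. The comparison
formula is isolated in one function so an alternative Laplacian
comparison can be substituted without touching the pipeline.

A degenerate pose (all joints coincident) has no distance structure: if
exactly one frame member is degenerate the score is defined as 0 with a
warning; two degenerate poses count as identical.

### Motion generator

Arm movement is modelled as sums of 2-4 random-phase sinusoids
(0.05-0.4 Hz) on the elbow and wrist angles -- smooth, band-limited,
human-plausible trajectories with controllable vigour. In the
synchronized regime the confederate's pose is the participant's pose
reflected about the inter-person axis, delayed by the follower lag
(default 0.1 s) and perturbed by keypoint noise (default 4 px); in the
control regime the two people move independently, each taking one turn as
sole mover while the other sits nearly still (small postural sway), which
is why control dyads score well above zero -- two quiet torsos are
themselves a form of similarity. Keypoint dropout (confidence 0) occurs
at 2% by default. One deliberate simplification: the reflected copy keeps
the same joint labels rather than swapping left and right. Anatomically a
mirror swaps handedness, but the pose-distance representation is
reflection-invariant, so same-label correspondence is what makes a
perfect mirror score exactly 1 -- the property the scorer's calibration
anchors to. The generator does not render video, model occlusion, or
produce pose-estimation artefacts beyond i.i.d. jitter and dropout, so
passing calibration here shows the scorer behaves as designed on clean
mirror-game geometry, not that it is robust to real video pathologies.

## Go/NoGo behaviour

### Generator

The schedule generator reproduces the task timing exactly (2-s block cue,
500-1500 ms jittered fixation, 1000-ms response window, 16-22 s jittered
inter-block intervals, block order randomized by seed). RTs are drawn
from a lognormal with participant random intercepts and block-type random
slopes; log-scale spreads are derived from millisecond inputs by the
coefficient-of-variation approximation at the grand mean, and cell means
are mean-preserving (the arithmetic mean of each group x block-type cell
equals its target). The default cell means are 230.0 / 248.1 / 376.8 /
394.9 ms (Control/Synchronized x AllGo/Mixed): these keep the Control
AllGo mean at the descriptive reference 230 ms while making the marginal
block-type effect 146.8 ms and group effect 18.1 ms in expectation --
matching the model-scale effects the analysis is meant to recover. The
raw Mixed-block descriptive means implied by these defaults are ~10 ms
above the descriptive reference table; the two sets of published numbers
are not jointly attainable from one generating distribution, and the
model-scale effects take precedence because they are the quantities under
recovery. Between-participant spreads default to 8 ms (intercept) and
5 ms (block slope): deliberately tighter than raw between-participant
descriptive SDs, consistent with the narrow credible intervals reported
for the group effect, which imply that most of the raw between-person
spread sits in within-person and block-level variation.

Commission errors are generated per Mixed block as Poisson counts from a
participant-specific rate (lognormal heterogeneity, sigma = 0.38, chosen
so the count SD matches the descriptive 8.8 at a mean of 19.7 per 80 NoGo
trials), truncated at the 4 NoGo slots per block; truncation loss is
under 2% of the mean at default rates. A per-trial Bernoulli option
exists for stress testing. Go omissions occur at 1%.

### Models

All models are hierarchical Bayesian fits by Gibbs sampling (JAGS),
2 chains, with convergence flagged when any monitored Rhat exceeds 1.05
(the fit is returned with `converged = FALSE` and a warning rather than
withheld outright, so diagnostics remain inspectable). Priors are weakly
informative and configurable: wide normals on coefficients (SD 1 on the
log scale), a low-information Wishart on random-effect precision, uniform
on residual SDs. The pilot-derived priors of the original analysis are
not available; these defaults let the data dominate.

* **RT**: `log RT ~ 1 + Group*BlockType + (1 + BlockType | participant)`
  on responded Go trials only (omissions and NoGo responses are excluded:
  standard Go/NoGo practice, and the lognormal support requires observed
  positive RTs). Treatment coding: Control = 0, Synchronized = 1,
  AllGo = 0, Mixed = 1. The sampler uses hierarchical centring
  (participant effects drawn around the group-level cell structure),
  which removes the intercept/random-intercept random walk that plagues
  the flat parameterisation. Millisecond-scale effects are differences of
  posterior marginal means, `exp(cell mean + total log-variance / 2)`,
  marginalised over random effects.
* **CE**: `counts ~ 1 + Group + (1 | participant)`, Poisson with log
  link. The rate is parameterised per 80 NoGo trials with the actually
  seen NoGo count as exposure offset, so reduced schedules still report
  on the full protocol's count scale; the count-scale group effect is the
  difference of marginal mean counts (Control minus Synchronized), also
  expressed as an error-rate percentage (counts / 80 x 100).
* **RT-CE (exploratory)**: per-participant commission counts with mean RT
  (centred, ms) as covariate and a participant intercept absorbing
  overdispersion; the grouping is per participant, the only structure
  available at one count per person. The slope is in log-counts per ms:
  -0.005 means ~e^(-1) fewer expected errors per +200 ms.
* An optional standardized extraversion covariate (questionnaire total:
  10 extraversion items 1-5 plus 10 self-esteem items 0-3, negative items
  reversed) can be added to the RT model; it is off by default since the
  study-level analyses found no meaningful contribution.

95% credible intervals are highest-posterior-density intervals: the
shortest window of `ceil(0.95 n)` sorted draws (valid for the unimodal
posteriors these models produce; ties break to the smallest lower bound).
Model comparison uses PSIS-LOO (Pareto-smoothed importance sampling
leave-one-out), implemented in-package: per-observation importance
ratios from the stored pointwise log-likelihood, generalized-Pareto tail
smoothing (Zhang-Stephens profile posterior fit with the usual weak
shape prior, 20% tail), elpd differences with their pointwise standard
error and Pareto-k diagnostics.

## fNIRS first level

The forward generator works at the acquisition rate (4.5 Hz) in
concentration space: per-ROI evoked responses are a 16-s boxcar at each
block onset convolved with the canonical double-gamma HRF (peak 6 s,
undershoot 16 s, ratio 1/6), scaled so an isolated block peaks at 1 --
amplitudes are therefore in concentration units (uM; defaults 0.8 uM
AllGo, 1.2 uM Mixed for HbO, HbR at the canonical -1/3). Systemic
contamination is shared across channels with random per-channel gains and
has three components: a slow drift (0.004 Hz plus a linear trend), a
Mayer wave (0.095 Hz), and broadband slow vasomotion (random sinusoids,
0.015-0.08 Hz). The vasomotion term matters: it overlaps the task band
above the drift cutoff, so it is the component that only short-channel
regression can remove -- without it, short channels would look useless
because drift regressors and orthogonality absorb everything else.
Instrument noise is AR(1) (default rho 0.6, marginal SD 0.4 uM).
Short channels (8 mm) carry systemic plus noise but no evoked component.
Concentrations are forward-converted to two-wavelength intensity through
the modified Beer-Lambert law so the analysis pipeline's inversion is the
generator's exact inverse.

The analysis chain:

1. **Downsample** 4.5 -> 0.6 Hz: zero-phase 4th-order Butterworth at
   0.3 Hz (protecting against aliasing Mayer-wave energy), then
   interpolation onto the 0.6 Hz grid. The filter is applied after mean
   removal with odd-reflection padding, so constants pass through exactly
   and edge transients are suppressed.
2. **Optical density**: `OD = -ln(I / mean(I))` per channel/wavelength.
3. **Modified Beer-Lambert law**: solve the 2x2 extinction system per
   sample with separation (cm) x partial pathlength factor 0.1 (the
   combined DPF 6 / PVC 60 factor); extinction coefficients at
   760/850 nm are shipped constants from the standard compilation used
   by NIRS toolboxes.
4. **Design matrix**: task regressors per condition; a DCT drift basis up
   to 0.01 Hz (the cosine set is the customary choice where the basis is
   not otherwise specified); all principal components of the converted
   short-channel series, computed per chromophore (whether the original
   analysis entered them per chromophore or jointly is not stated;
   per-chromophore is implemented and isolated); and a constant. Task
   regressors are built at the acquisition rate and passed through the
   *same* anti-alias operator as the data: downsampling is linear, so
   this makes noise-free amplitude recovery exact to machine precision
   despite the non-integer 7.5x decimation.
5. **AR(1) GLM** per channel x chromophore: OLS, lag-1 residual
   autocorrelation, Cochrane-Orcutt prewhitening, refit (one pass by
   default; iterations configurable). Standard errors come from the
   whitened fit; in the noise-free limit they are floored at 1e-12 so
   inverse-variance pooling stays defined.
6. **Channel selection and ROI pooling**: keep 20-40 mm separations,
   then pool within ROI with weights 1/SE^2 (pooled SE =
   (sum of weights)^(-1/2)); an ROI with no surviving channel is
   reported missing, never zero-filled.

## Second level

Per-participant ROI amplitudes enter a multivariate Gaussian model:
`(HbO, HbR) ~ BlockType * ROI * Group` with participant intercepts and
block-type slopes for both chromophores drawn from one correlated
4-dimensional distribution (the shared "|p|" linkage) and a free 2x2
residual covariance capturing the HbO-HbR correlation. The fixed-effect
side is parameterised directly as cell means (block x ROI x group per
chromophore) -- equivalent to the full treatment-coded interaction model
and the natural input to marginal contrasts. One identification detail:
with mean-zero random effects the split between cell means and average
participant effects is informed only by the prior, which Gibbs samplers
traverse slowly. The package therefore monitors the likelihood-identified
estimand -- each cell mean plus the average random effect of that cell's
group -- and builds all summaries and contrasts from those draws; this is
a change of monitored quantity, not of model.

Contrasts are equal-weight marginal cell-mean differences (the design is
balanced by counterbalancing): AllGo - Mixed per ROI with groups
combined (positive = AllGo more positive), and Control - Synchronized
per ROI x block type (positive = Control more positive). Each contrast
is flagged `substantial` when its 95% HPD excludes zero and `trend` when
zero lies outside the 90% but inside the 95% HPD -- the "tail"
designation has no published quantitative definition, so this 90/95 rule
is the package's documented operationalisation.

The HbO-HbR difference `d = beta_HbO - beta_HbR` per participant, ROI and
block type synthesises each pair into one value: positive = canonical
response, negative = inverted (negative-BOLD-like) response. Each pair is
classed *negative* (sign-discordant HbO and HbR, the pattern expected of
cortical activity) or *positive* (sign-concordant, the pattern expected
of systemic origin). How a pair's "correlation" should be computed from
two point estimates is not defined in the source analysis; sign
opposition is the only per-pair notion available and is implemented as an
isolated, replaceable rule. The difference model is the univariate
analogue of the multivariate fit, optionally restricted to
negative-class pairs (the conservative analysis); cells emptied by the
filter are flagged and their contrasts suppressed, and class proportions
per cell are always reported. The brain-behaviour model adds per-cell
slopes of the difference on the participant's mean RT and commission
count (standardized internally, reported per original unit); its
published random-effects term is typeset ambiguously and is read as
`(1 + BlockType | participant)`, the only well-formed interpretation.

## Orchestration and problem sizes

`run_pipeline()` executes schedule -> behaviour -> motion/similarity ->
fNIRS (first + second level) -> report from one configuration object with
a single master seed (per-stage seeds derived deterministically), writes
CSV outputs plus a hash manifest, reuses cached stage outputs when
parameters and inputs are unchanged, and refuses to build on modified
intermediates. End-to-end determinism holds at fixed seed and fixed
sampler settings.

The validation suite runs at reduced scale chosen to keep recovery
informative: behavioural recovery at 20 participants/group and 20 blocks
(10 and 30 replicate fits for RT and CE respectively; replicate averages
are reported because a single simulated cohort of this size carries
+-2-3 ms / +-2 count sampling noise in the group contrasts); descriptive
calibration at 400/group over the full 40 blocks; pose calibration over
10 dyads per regime at full length (5 min at 30 fps); fNIRS recovery at
15 participants/group, 10 blocks, 2 long channels per ROI, with the
short-channel benefit quantified over 100 paired replicates as an RMSE
ratio. The acceptance script repeats these protocols from scratch at the
same sizes.

## Known limitations

* The Laplacian comparison reproduces the documented formula family, not
  the exact adapted scripts of the original manipulation check; the gain
  constant is a packaged calibration, and real-video pathologies
  (occlusion, identity switches, non-mirror partial imitation) are
  outside the generator's scope.
* Generated commission counts are truncated at 4 per block; at rates far
  above the defaults the truncation bias becomes material.
* The CE count model assumes Poisson variation around lognormal
  participant rates; zero-inflation or block-serial effects are not
  modelled.
* The first level implements no motion-artifact correction and no
  channel-quality metric beyond the separation filter, matching the
  analysed pipeline.
* Gibbs sampling with weakly-informative Wisharts can mix slowly for
  random-effect covariances at very small cohort sizes; the convergence
  flag should be respected.
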