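---
title: "Closed-loop error damping: models, simulator design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop error damping: models, simulator design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcidamp)
```

## The problem

Intracortical brain-computer interfaces decode motor intent from
population spiking to drive a cursor, and even well-calibrated linear
decoders produce epochs of *erroneous control* in which the cursor moves
away from its target. Motor cortex carries a detectable correlate of these
errors — partly even *before* the error is visible in the kinematics — and
a linear classifier running in parallel to the movement decoder can use it
to damp the decoded velocity in real time, trading a little speed for
substantially straighter, more reliable control.

`bcidamp` implements that whole loop as a reproducible simulation plus the
offline analyses used to characterize it: kinematic error labeling, a
pooled-variance naive Bayes error classifier with cross-validation across
time and across targets, detection-delay analysis, real-time velocity
damping with an ON/OFF set harness, closed-loop performance metrics, and
population-geometry comparisons (subspace alignment with a chance level,
PCA dimensionality, participation ratio, Gaussian mutual information,
linear intent reconstruction, LDA projection).

## Error definition and labeling

At each 20 ms bin the *motor intent* is the vector from the cursor to the
current target, `v = target - cursor` (`motor_intent()`), and its
magnitude is the instantaneous cursor-to-target distance. A bin is labeled
*erroneous control* exactly when that distance increased relative to the
previous bin; ties — a stationary cursor — count as correct, since a
non-moving cursor is not an increasing error. The *pre-error* window is
the 200 ms of correct control immediately preceding each correct-to-error
transition (`mark_pre_error()`), truncated at the trial start or at an
earlier bout.

Classifier features are per-channel mean smoothed rates over 80 ms
non-overlapping windows (4 bins at 50 Hz). A window is erroneous when the
distance at its last bin exceeds the distance just before its first bin —
the distance increased *while the features were recorded* — and windows
whose bins are majority pre-error become pre-error windows. Sets are
screened before training: only sets with at least 30% erroneous windows
are retained (`filter_sets()`, threshold exposed because a well-performing
user may need a lower one).

## The synthetic population

No public recordings exist for this paradigm, so all inputs come from the
generator, which emulates the statistical structure the analyses assume:

* **Spiking**: `n_channels = 176` channels emit independent Poisson counts
  at 50 Hz with rate `max(0, b_i + d_i (p_i . v) + L_i e)`: a baseline
  (10 Hz mean), cosine tuning to the commanded velocity (depth 15 Hz per
  unit speed, preferred directions uniform on the circle), and a rank-2
  error-latent loading. Threshold-crossing extraction from broadband
  voltage is deliberately not simulated; the analyses consume binned
  counts only.
* **Smoothing**: counts are convolved with a causal decaying-exponential
  kernel truncated at 440 ms with decay constant 440/3 ms and normalized
  to unit sum, so a constant input converges to its true rate. (The
  alternative reading — 440 ms as the decay constant itself — would give a
  materially laggier filter; the truncated-support reading keeps the
  closed loop responsive and is the one implemented.)
* **Task**: center-out with 8 radial targets on a ring of radius 0.8 in
  the `[-1, 1]^2` workspace, success radius 0.12, alternating reach and
  center phases, 8 s timeout per phase. The commanded speed is 0.8
  units/s, scaled down linearly within 0.15 units of the target
  (proportional control), with isotropic command noise (sd 0.1 units/s).
* **Errors**: disturbance events arrive as a Poisson process (0.6 events/s,
  0.9 s duration). During an event a velocity offset of 1.2 units/s in a
  per-session *bias direction* (plus 30 degrees of per-event jitter) is
  added to the decoded cursor velocity. Because the disturbance enters on
  the decoder side, the spiking population carries no movement-direction
  signature of the error itself — with the latent silenced
  (`error_gain = 0`) the classifier has nothing legitimate to detect,
  which is what makes the package's negative control meaningful. The
  decoder-side disturbance still reproduces the session-specific
  directional bias of real error epochs and the sub-uniform direction
  entropy of the control signal.
* **Error latent**: a scalar state `e(t)` rises above 0.5 as soon as the
  *lead window* starts — 200 ms before the disturbance acts on the cursor
  — ramps to 1 at kinematic onset, fluctuates high (slow AR(1), ~0.5 s
  correlation time so its variance survives the 440 ms smoothing) during
  the event with per-event amplitude heterogeneity, and decays with a
  100 ms constant afterwards. Between events it sits at a sub-threshold
  baseline fluctuation (mean 0.15, sd 0.12): error-monitoring activity is
  never exactly silent, and this along-loading noise is precisely what
  keeps error detection at a realistic margin instead of being trivially
  separable across 176 channels.
* **Two loading patterns**: the latent is expressed through a rank-2
  loading (per-channel scale `error_gain = 40` Hz). The *anticipation*
  pattern carries the latent during the lead window and only weakly during
  the event; the *execution* pattern carries it once the error manifests.
  A classifier trained without pre-error windows therefore assigns the
  anticipation pattern almost no weight and cannot fire before kinematic
  onset, while pre-error-inclusive training genuinely buys earlier
  detection — the mechanism behind the detection-delay contrast.
* **Command degradation**: while the latent is high the user's command
  loses gain (80% at full latent), direction-neutrally. This is what
  reduces intent information (mutual information and linear
  reconstruction) during pre-error and error epochs without writing any
  direction signal into the population.
* **Recording instability**: preferred directions rotate between sets by a
  session-consistent random drift (sd 3 degrees per set by default). This
  is why the two-step calibration helps: the closed-loop refit sees a more
  recent tuning state than the observation fit.

Everything is reproducible bit-for-bit from `(config, seed)`.

### What the generator does *not* emulate

Spike waveforms, cross-channel noise correlations beyond the shared latent
and command drive, non-Poisson firing statistics, learning or adaptation
by the user, click/grasp decoding, and electrode dropout. Passing tests
therefore show that the *analysis pipeline* recovers the stated phenomena
from data with the assumed structure — they are not evidence about any
particular real recording.

## Decoder

The movement decoder is factor analysis (20 factors, maximum-likelihood EM
on smoothed rates; constant channels excluded with a warning; the EM
log-likelihood trace is stored and non-decreasing) followed by a Kalman
filter whose state is the 2-D velocity only — no position or bias term,
matching a velocity decoder. The observation map is fit by least squares
of factors on intent velocity with a ridge fallback, the state transition
is a damped identity from the velocity autoregression, and noise
covariances come from residuals. An output gain matches the mean decoded
speed to the mean intent speed on calibration data. The filter state is
reset at each trial start (cross-trial carryover is a free choice; reset
is the conservative one).

Calibration is two-step (`calibrate_decoder()`): an *observation* set in
which the cursor moves itself and the user imagines following it, then a
*closed-loop* set driven by the observation decoder with all velocity
orthogonal to the target direction fully clamped (`attenuation = 0`,
movement confined to a line), refit against the intended towards-target
velocity.

## Classifier and modulation

The classifier is Gaussian naive Bayes with pooled (class-shared)
per-feature variances, so the decision function is linear; a
class-specific-variance variant sits behind `pooled = FALSE`. Variances
are floored at `1e-6` times the median feature variance. Because there are
176 correlated features and only a few hundred training windows, the class
means are regularized by nearest-shrunken-centroids: each standardized
class-mean difference is soft-thresholded at `sqrt(2 log p)` times its
standard error (the universal threshold, so it needs no tuning), with the
standard error inflated by an effective-sample-size factor from the mean
lag-1 autocorrelation of the features, since windows are serially
correlated through the smoother. On an
uninformative population this zeroes essentially every weight and the
classifier falls back to the prior — no false alarms — while genuine
error-signal features pass untouched.

The error flag is `probability >= tau` with `tau = 0.85`, *inclusive* (the
threshold is reached, not exceeded); the posterior distribution is
strongly bimodal on separable data, so results are insensitive to `tau`.
During closed-loop control the probability is evaluated once per completed
80 ms window and the resulting flag damps all four bins of the following
window (a causal update cadence; the update could equally be per-bin, but
the window cadence matches the feature definition). Damping multiplies the
decoded velocity by 0.30, preserving direction.

Evaluation conventions: in the pre-error-inclusive condition, pre-error
windows count as error both in training and in held-out accuracy; in the
error-only condition they count as correct in both. Cross-validation
across time uses 8 contiguous blocks (temporally adjacent windows are
correlated; contiguous folds avoid leakage — random folds would flatter
the accuracy). Cross-validation across targets holds out all trials of one
of the 8 target positions per fold. Chance is the greedy majority-class
level. Detection delay is measured per error bout as the time from the
first error-labeled window to the first flag, searching from the end of
the previous bout so pre-onset flags give negative delays; undetected
bouts are excluded from the mean and reported as a detected fraction.

## Subspace analyses

All population comparisons work on the labeled 80 ms window features.
`alignment_index()` is the symmetrized fraction of one epoch's variance
captured by the other's top-10 principal subspace, normalized by the sum
of the top-10 singular values of the target covariance, so it is 1 for
identical hyperplanes and 0 for orthogonal ones. Its chance level joins
the two datasets, cuts them into 40 contiguous chunks, and realigns random
half-splits (100 repeats by default): an observed index below that
distribution means genuine misalignment. Dimensionality is reported both
as the number of principal components reaching 80% cumulative variance and
as the participation ratio `(sum lambda)^2 / sum lambda^2`.

Estimation choices that matter at desk scale: each epoch class is
mean-centered separately; the correct and error classes are subsampled to
a common size so estimation bias is shared (the scarcer pre-error class
keeps its own count and its rows should be read accordingly); and mutual
information and intent reconstruction are computed after projecting onto
the top-20 principal components of the pooled data — one shared basis for
all epochs — because a 178-dimensional Gaussian MI estimate from a few
hundred samples is dominated by bias. Covariances in the MI computation
can be regularized by adding `1e-6` of the mean diagonal; analytic
covariances need none, and reported MI is floored at zero. The intent
regression is the ordinary least-squares reconstruction of the intent
matrix from the neural matrix, scored as the mean Pearson correlation of
the x and y components, with a small ridge engaged automatically when the
Gram matrix is ill-conditioned. The LDA projection shrinks the
within-class scatter towards a scaled identity (10% by default) before
solving the generalized eigenproblem.

## Problem sizes and test design

The packaged tests exercise the pipeline at the study's own per-session
scale: sessions of 40 full center-out trials (80 phase records, roughly
5,000–7,000 bins over 176 channels), two-step calibration from 40-record
sets, 8-fold cross-validation, and paired comparisons across 12
independently seeded sessions; ON/OFF comparisons
use matched pairs — the same session seed and tuning run once per policy —
and the hold task 24 trials per condition. Unit tests use
smaller populations (24–48 channels) where the property under test does
not depend on the population size. The two-step-calibration comparison is
probed under strong drift (20 degrees per set) and a tight 1.6 s timeout,
because with mild drift and a generous timeout both decoders sit at a 100%
success ceiling and the comparison would be vacuous.

## Known limitations

* The kinematic error definition is a proxy; orbiting or corner
  geometries can label poor control as correct. The angular-error
  validation (higher angular error in error-labeled windows) is the
  package's guard that the labels still separate good from poor control.
* Gaussian MI on window features is a biased estimator at these sample
  sizes; only within-session, equal-n comparisons are meaningful, not
  absolute values in nats.
* The generator's error latent is a two-pattern abstraction; real
  error-related activity is unlikely to be exactly low-rank, and the
  dimensionality-collapse effect size here is set by the chosen
  `error_gain`.
* The hold task shares its generator with the center-out task, so
  classifier generalization across tasks is a weaker claim than
  generalization across visual environments would be.
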