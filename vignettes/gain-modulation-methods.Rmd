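---
title: "Expectation, adaptation and orientation coding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expectation, adaptation and orientation coding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predgain)
```

`predgain` implements, end to end, the computational machinery used to ask
how *expectation* shapes orientation coding in primary visual cortex:
grating-sequence designs with controlled predictability, synthetic
calcium-imaging recordings carrying a known expectation effect,
single-neuron tuning quantification, population decoding by inverted
encoding, cluster-corrected permutation statistics, and a six-channel
gain-modulation model in which adaptation and expectation jointly control
channel sensitivity. This vignette explains the scientific content of each
piece: the models, their assumptions, the tunable parameters, the numerical
choices, and what the synthetic data can and cannot show.

## Stimulus sequences

Gratings take one of six orientations (0-150 degrees in 30-degree steps),
shown at 4 Hz for 250 ms each with no gap. Three regimes are generated:

* **random** -- each orientation independent of the last (optionally an
  exactly balanced shuffle). No transition is predictable.
* **rotating** -- the orientation steps by 30 degrees per presentation,
  clockwise or anticlockwise, for a run of 5-9 presentations, then jumps to
  a random orientation *other than the predicted continuation* (an
  expectation violation), after which rotation resumes in the opposite
  direction from the landing orientation. Within-run events are *expected*;
  the jumps are *unexpected*.
* **rotating_control** -- identical, except that one extra random jump
  follows each violation before rotation resumes. This decorrelates the
  stimuli that follow a violation from the violation itself, which matters
  for slow-indicator analyses (below).

Run lengths are uniform on 5..9 (the design states only the range). The
unexpected orientation is drawn uniformly from the five orientations other
than the predicted one; excluding also the previous orientation is possible
via the sequence statistics but is not done, matching the transition
statistics of the random regime. Orientations are stored in degrees with
period 180; signed differences live in (-90, 90]. The *expectation
violation* of a jump is the circular distance between predicted and
presented orientation (30, 60 or 90 degrees here), signed when the side
matters.

Transition labels are a pure function of the orientations plus the regime:
`label_transitions()` re-derives them by walking the sequence, and
re-labelling a labelled sequence is the identity (a property the tests
exercise).

## Synthetic recordings

`simulate_population()` draws per-neuron generative parameters: preferred
orientation uniform on [0, 180), circular-Gaussian tuning with width around
40 degrees, log-normal tuning gains (median 40 dF/F%), baseline ~5 dF/F%. A
fixed fraction (default 0.273) of neurons is orientation selective; the
rest are flat. Selective neurons carry a multiplicative gain factor
(default 1.3) applied on unexpected events only -- the generative mirror of
the effect the analyses are designed to detect, and the ground truth for
recovery tests.

`simulate_responses()` holds each event's drive
(`baseline + gain * G(orientation - preferred)`) for its 250 ms slot,
convolves with a causal single-exponential calcium kernel
(`kernel_tau_ms`, default 400 ms, a GCaMP6f-like decay; the kernel is
unit-sum so a sustained drive of 1 reads out as 1), and adds Gaussian noise
(default sd 15 dF/F% per frame) with a shared low-rank component
(`noise_corr`, default 0.2, three random factors) so that the decoder's
covariance shrinkage faces realistic correlated noise. The noise defaults
are calibrated, once, so that the injected effect is recoverable at the
package's standard analysis scales; they are not fitted to any real
recording.

`extract_epochs()` cuts frame-aligned epochs (default -500..2000 ms) and a
scalar per-trial response: the mean dF/F over a post-onset window (default
250-1000 ms, evaluated on absolute frame times, hence 22 or 23 frames at
30 Hz depending on onset phase; the count is logged). Edge trials that do
not fit are dropped with a message.

### What the simulator does not capture

The drive model is deliberately minimal: no spiking, no within-presentation
adaptation, no response suppression by preceding similar stimuli. One
consequence is worth understanding because it shapes two analysis choices.
At 4 Hz with a 250-1000 ms window, a trial's scalar response contains the
calcium responses of the *three following* stimuli at comparable weight to
the current one. In random sequences those neighbours are uniform and wash
into the fitted offset. In plain rotating sequences, the stimuli that
follow a violation rotate away from it, so the bleed is *correlated* with
the violated trial's orientation and systematically widens the measured
unexpected-condition tuning; real V1 suppresses such repeats (rapid
stimulus-specific adaptation), synthetic neurons do not. The package
therefore:

1. uses **rotating_control** sessions for tuning and decoding comparisons
   (the control design exists precisely to decorrelate the post-violation
   stimuli), and
2. performs condition *decoding* comparisons **time-resolved** (per frame,
   as in the time-course analyses) rather than on the window scalar, since
   early evoked frames (~30-300 ms) isolate the current stimulus.

Passing tests on synthetic data therefore demonstrate that the analysis
chain recovers a known gain effect under realistic noise and calcium
dynamics; they do not demonstrate anything about biological mechanism, nor
that real data are free of the bleed-through confound (real control
conditions address that).

## Single-neuron tuning

Tuning curves are the scalar responses averaged per orientation, fitted
with a circular Gaussian with constant offset,

$$G(x) = A \exp\!\left(-\frac{d(x,\phi)^2}{2\sigma^2}\right) + C,$$

by Levenberg-Marquardt least squares, with gain \(A \ge 0\), width
\(\sigma \in [5, 120]\) degrees, multi-start initialisation
(\(\phi_0\) at the peak orientation, \(\sigma_0 = 40\)). By default
\(d(\cdot,\cdot)\) is the circular orientation distance, so curves peaked
near the 0/180 boundary are represented correctly and a wrap index merely
canonicalises \(\phi\) into [0, 180); the literal single-shift form
\(x - \phi - j\cdot180\) with \(j \in -4..4\) is available (`wrap = FALSE`)
for compatibility, but it cannot represent boundary-peaked curves (about
8% of a uniform population) and produced degenerate fits for exactly those
neurons. Fits whose width terminates at the bounds are flagged invalid: a
pinned width means the 6-point curve collapsed into a spike or a ramp, and
its "gain" is not interpretable.

Selectivity screening is a one-way analysis of variance of the scalar
response across the six orientations, run separately in the random and
unexpected trials; a neuron passes at p < 0.05 in either (no
multiple-testing correction, matching standard practice for this screen —
the implied joint false-positive rate \(1-(1-\alpha)^2 \approx 9.75\%\) is
verified by simulation in the tests). Note that with overlapping scalar
windows the trialwise errors are serially correlated, which inflates the
screen slightly; the screen is a filter, not an inference.

The **surprise effect** is the per-neuron difference in fitted gain, random
minus unexpected (negative when surprise enhances the response), defined
only where both fits are valid. Orientation-selectivity time courses use
the weighted circular mean on doubled angles, weights equal to the tuning
curve minus its minimum (the weighting is not uniquely determined by the
construction; this choice makes a flat curve carry zero orientation
signal and is configurable at the call site).

## Population decoding (forward / inverted encoding)

Nine half-cosine-to-the-eighth basis functions centred at 0, 20, ..., 160
degrees tile orientation space (because \(\cos^8\) contains harmonics only
up to order four, nine equally spaced channels tile *exactly*). Training
solves `B1 = W C1` for the neurons-by-channels weight matrix. With six
distinct stimulus orientations the design spans only a six-dimensional
channel subspace, so the joint normal equations are singular; the default
therefore estimates each channel's weights separately by least squares,
with the joint solution available (`method = "joint"`) for full-rank
designs and used as an oracle check in the tests.

Inversion estimates test-trial channel responses by the minimal-norm
least-squares inverse of the weights (SVD pseudoinverse; the same rank-six
structure makes a plain \((W^TW)^{-1}\) impossible), after whitening by the
residual noise covariance estimated with Ledoit-Wolf shrinkage towards its
diagonal (shrinkage intensity is closed-form; whitening is skipped for
numerically zero residuals). Channel responses are expanded through the
basis onto a 1-degree grid; the decoded orientation is the doubled-angle
vector sum over the profile; the error is the signed circular difference
from the presented orientation; and **decoding accuracy** is the resultant
length of the error distribution (1 = perfect, 0 = chance).

Cross-validation uses stratified folds (each orientation spread as evenly
as possible over folds; 10 folds by default, configurable), so every trial
is tested exactly once; population-size analyses redraw random neuron
subsets (24 by default) per size. On a noiseless population whose responses
are exact channel tuning curves the whole chain decodes with zero error to
machine precision -- a symmetry property (reflection equivariance of basis,
design and estimator about any stimulus on the 30-degree grid) that the
acceptance tests verify.

## The channel gain-modulation model

The model is a bank of six orientation channels (preferred orientations
0-150 degrees, spacing 30), each with a circular-Gaussian *sensitivity*
profile of width 40 degrees and unit gain. The measured response of a
channel to a grating is its sensitivity state times the squared sensitivity
profile value,

$$r_k(t) = S_k(t)\, G_k(x_t)^2,$$

an expansive squaring output nonlinearity in the tradition of V1 energy
models. The squaring matters quantitatively: the response profile then has
an effective width of \(40/\sqrt2 \approx 28\) degrees, which is what the
Gaussian fits of the model's condition curves return (~28-31 degrees);
with a linear read-out every fitted width would equal the 40-degree channel
width, which is inconsistent with the condition statistics this model is
meant to reproduce. With all states equal, the doubled-angle vector average
of the population response equals the presented orientation exactly on the
stimulus grid (harmonic leakage off the grid is below 0.05 degrees).

Two gain sources modulate sensitivity before the stimulus arrives:

* **adaptation** -- each channel is reduced in proportion to its
  (peak-normalised) sensitivity to the previous stimulus:
  \(g^A_k = 1 - \gamma_A\,G_k(x_{t-1})\). Channels near the adapter are
  maximally reduced; orthogonal channels essentially untouched.
* **expectation** -- an *inverse copy* of the response tuning centred on
  the predicted orientation reduces stimulus-space sensitivity around the
  prediction: \(g^E_k = 1 - \gamma_E\,G_k(\hat{x}_t)^2\). The profile is
  response-shaped (squared) because the inverse copy is obtained by
  fitting the response profile and inverting it. On expected trials the
  prediction is correct, so the response to the presented orientation is
  suppressed; on unexpected trials the suppression lands 30-90 degrees
  away from what appears, which is what produces the gain enhancement.

The state evolves with per-trial maximum renormalisation and a persistence
exponent controlled by the modulation factor \(m\) (default 3):

$$S_t = \max\text{-normalise}\!\left(S_{t-1}^{\,m/(m+1)}\; g^A_t\; g^E_t\right),$$

floored at \(10^{-12}\) so that full suppression (\(\gamma = 1\)) remains
recoverable. The exponent form is a design choice -- the verbal description
of the recurrence underdetermines it -- selected so that (i) a single
adapting event remains detectable at least four trials later at
\(m = 3\) and fades much faster at \(m = 1\), (ii) the state recovers
towards 1 in the absence of modulation, and (iii) larger \(m\) gives longer
persistence. It is isolated in `run_model()` so alternatives can be swapped.

The expected orientation on each trial is the 30-degree continuation of the
current rotation; at a jump the model still expects the (wrong)
continuation, which is exactly what generates the unexpected enhancement.

### Condition statistics

`simulate_condition_statistics()` reproduces the study layout: 23 sessions,
each with two runs of 1800 presentations per condition; random sequences at
(adaptation 0.5, expectation 0) -- all the available gain assigned to
adaptation because nothing is predictable -- and rotating sequences at
(0.25, 0.25), the same total in equilibrium. Channels are aligned to their
preferred orientation, responses averaged within condition across both
runs, and the circular Gaussian fitted per session. At these settings the
across-session mean fitted gains order unexpected > expected > random
(~0.67 / 0.58 / 0.56 arb. units) and the widths order
expected > random ≈ unexpected (~31.0 / 28.3 / 27.9 degrees). The
session-to-session SD of a deterministic model at 3600 trials per
condition is small (< 0.01), so these means are stable to the third
decimal.

### Decoding bias ("repulsion")

Binning unexpected trials by signed violation and decoding the model's
population response shows the decoded orientation biased *away from the
expected orientation* in every bin -- the model's analogue of the
perceptual repulsion effect, and the direct consequence of suppressing
sensitivity around the prediction. At the combined rotating setting the
bias magnitude peaks at the ±60-degree bins (~1.3 degrees vs ~1.1 at ±30):
the persistent state carries suppression from the whole swept rotation arc,
which partially cancels the ±30 expectation repulsion. With the expectation
gain isolated (adaptation 0), the profile peaks at ±30 degrees, the
signature of a pure prediction effect. With expectation off entirely, the
model instead shows classic serial dependence: repulsion from the previous
stimulus in random sequences.

### Trial-level comparison against neurons

`regress_to_neurons()` regresses each neuron's trial series on the six
channel responses by ridge regression, with the penalty chosen per neuron
by generalised cross-validation (closed form via SVD -- six regressors make
this exact and fast), reporting betas, the best regressor per neuron, and
cross-validated variance explained. `model_comparison_grid()` sweeps gain
levels for adaptation-only, expectation-only, and combined (adaptation
fixed at 0.25) model variants; on synthetic neurons generated from a known
expectation gain the grid's variance explained peaks at the generative
level.

## Cluster permutation statistics

`sign_flip_cluster_test()` tests paired difference time series against
zero: one-sample t per timepoint, clusters formed at a two-sided threshold
(p < 0.05) as maximal same-sign supra-threshold runs, cluster mass the
summed t, and a null distribution of maximal absolute cluster masses from
random whole-series sign flips per unit (5000 by default). Flipping whole
series is the only exchangeability scheme that preserves within-unit
temporal autocorrelation. P-values use the add-one convention. Family-wise
error calibration is verified in the acceptance tests over 200 null
simulations at 1000 permutations (scaled from 5000 to keep the suite fast;
the calibration property does not depend on the permutation count beyond
resolution).

## Reproducibility and problem sizes

Every stochastic step takes an explicit integer seed; the pipeline derives
per-stage substreams from one master seed and records them in a manifest.
The default test and acceptance scales -- 23 model sessions of 2 x 1800
trials, 400 neurons x 2000 trials for effect recovery, 24 neuron draws of
200 for decoding, 200 null simulations for calibration -- were chosen to
match the study's stated design where it states one, and otherwise to make
sampling error comfortably smaller than the effects under test.

## Known limitations

* The generative drive model omits response adaptation, so plain rotating
  sequences carry a post-violation bleed confound at slow indicator time
  constants; use the control design for condition comparisons (the
  package's defaults do).
* The state recurrence of the channel model is one member of a family
  consistent with its verbal description; conclusions that depend on the
  exact persistence profile (rather than its ordering in \(m\)) should be
  checked against alternatives.
* Width estimates from single 6-point tuning curves carry several percent
  sampling noise at realistic trial counts; condition comparisons of width
  should aggregate per-neuron fits, as the package's summaries do.
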