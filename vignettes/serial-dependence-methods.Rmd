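---
title: "Measuring serial dependence on a circular face-morph continuum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring serial dependence on a circular face-morph continuum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialdep)
```

## The problem

Serial dependence (SD) is the systematic attraction of a current perceptual
report toward recently seen stimuli. `serialdep` analyses SD in
continuous-report ("adjust to match") experiments in which each trial shows
two face images drawn from a circular morph continuum — an *inducer* and a
*target* — and the observer later reproduces the target by steering an
adjustment face around the wheel. The attraction of the response toward the
inducer, as a function of how far the inducer sat from the target, is the
quantity of interest.

Two experimental designs are supported. In the first, the reported face is
always the second one; trials cross the inter-stimulus interval (ISI: 1, 3,
6, 10 s) with the response delay (0, 1, 3, 6, 10 s), 20 conditions at 180
trials per session. In the second, the ISI is fixed at 1 s and a postcue
decides which of the two faces to reproduce; trials cross the postcued
target with delays of 1, 3, 6 s, 6 conditions at 300 trials per session.

## Stimulus geometry

The morph wheel interpolates `n_between = 46` images between each pair of
three anchor identities, giving 141 positions. All positions are 0-based
integers; anchors sit at 0, 47, 94. Distances are *signed shortest circular
distances* in morph steps, positive in the direction of increasing index.
On the odd 141-wheel every distance is unique in \[-70, 70\]; for even
wheels (a generalisation the package permits) the antipodal tie goes to
`+n/2` by convention. Which pictorial direction is "clockwise" is
irrelevant to every statistic in the package — all of them are equivariant
under mirroring — so the index-increasing convention is simply documented.

Each anchor is the prototype of a category extending ±23 steps around it;
3 × 47 positions tile the wheel exactly. The constructor refuses
non-tiling half-widths unless explicitly overridden, because the
categorical analysis below relies on the partition.

## Per-trial derivation and filtering

For each trial the *adjustment error* is the signed distance from the
target to the response, and the *stimulus difference* is the signed
distance from the target to the inducer. Trials with response times above
15 s or absolute errors above 60 steps are treated as lapses and removed;
both thresholds are strict (a trial at exactly 15.0 s or exactly ±60 steps
is kept), and a trial failing both criteria is counted once. Data are
pooled across participants before fitting; the trial table keeps
participant and session labels so users can subset if they prefer
per-participant fits.

## The derivative-of-Gaussian bias curve

The bias curve relating stimulus difference $x$ to the expected adjustment
error is the classic DoG of the SD literature:

$$y(x) \;=\; \alpha\,\frac{x-\mu}{\sigma^{2}}\,N(x;\,\mu,\sigma),$$

with $N$ the normal density. Up to sign this is the first derivative of a
Gaussian; the sign is fixed so that **positive $\alpha$ means attraction**
(errors share the sign of $x$), which also makes the sign of the
half-amplitude equal the sign of $\alpha$. Writing the model as
$-\alpha f'(x)$ rather than $+\alpha f'(x)$ is deliberate: the verbal
definition of the curve in the SD literature multiplies the density by $x$,
and $x\,f(x) = -\sigma^{2} f'(x)$, so this parameterisation is the one
under which "positive = attractive" holds. The algebra also fixes the
model's symmetries: negating $x$ alone maps $(\mu,\sigma,\alpha)$ to
$(-\mu,\sigma,-\alpha)$ (attraction flips), while negating both $x$ and
$y$ maps to $(-\mu,\sigma,\alpha)$ (attraction is preserved — mirroring
both axes is a pure relabelling of the wheel). The test suite asserts both
equivariances.

The **half-amplitude** — the height of the curve from peak to zero — is
the scalar SD magnitude. For $\mu = 0$ it has the closed form
$\alpha\,e^{-1/2}/(\sigma^{2}\sqrt{2\pi})$ at $x = \pm\sigma$;
`dog_half_amplitude()` instead maximises $|y|$ numerically on the
\[-70, 70\] domain (grid bracket + golden-section refinement) so it stays
correct when $\mu \neq 0$, and matches the closed form to better than
1e-9 relative when $\mu = 0$.

### Fitting

`fit_dog()` minimises the residual sum of squares under box constraints.
For fixed $(\mu, \sigma)$ the optimal $\alpha$ is a linear least-squares
coefficient and is profiled out (in compiled code, since the bootstrap
refits the model thousands of times), leaving a 2-parameter bounded search
run from 12 deterministic starting points (3 values of $\mu$ × 4
log-spaced values of $\sigma$) because the RSS surface is multimodal in
$\sigma$. Ties in RSS are broken toward the smaller $\sigma$. Defaults,
chosen once:

* $\mu \in [-20, 20]$ steps — the curve centre should sit near zero
  difference; a free $\mu$ absorbs small asymmetries, and `mu = 0` can be
  fixed for the odd-symmetric convention.
* $\sigma \in [3, 70]$ steps — below 3 the curve chases single-point
  noise; above 70 it exceeds the domain.
* $\alpha \in [-10^6, 10^6]$ — effectively unbounded on this scale.
* At least 10 pairs per fit; below that a condition is reported
  *non-estimable* rather than aborting the run.

Raw trial pairs are fitted (not binned means): binning by integer
difference would weight sparse extreme bins equally with dense central
ones; pooled raw trials keep the least-squares weighting proportional to
the data. A condition-mean reading of the same analysis can be had by
pre-aggregating the table before calling `fit_dog()`.

### Predictor variants

`build_predictor()` produces the four (x, y) constructions: the
within-trial difference (target → inducer), and three across-trial
variants where x is the signed distance from the current target to the
previous trial's Face 2, Face 1, or response. Across-trial variants drop
the first trial of each session and any pair touching an excluded trial.

## Bootstrap inference

Uncertainty comes from resampling *trial pairs* with replacement at the
original n (the analyses pool participants, so the trial is the natural
exchangeable unit), refitting the statistic on each resample, and reading
the 95% interval off the empirical distribution. Half-amplitudes use the
percentile interval by default; the categorical index defaults to BCa
(bias-corrected and accelerated, with jackknife acceleration), matching
the canned CI routines typically used for that statistic. An estimate is
*significant* when its interval excludes zero. Note that this flag is
conservative at the null: when the true amplitude is zero the sign of the
fitted half-amplitude is noise-driven, the resampled statistics span both
signs, and the 95% interval almost always straddles zero — so the
false-positive rate sits below the nominal 5% (the null-calibration study
in the test suite measures it). This is a property of the CI-based
decision rule itself, not of this implementation. Resample fits that fail are
counted, logged, and excluded from the quantiles; failure on more than 20%
of resamples aborts with a diagnostic. Bootstrap refits of the DoG are
warm-started from the full-sample solution plus two spread starts — the
full multi-start grid on every resample would cost ~4× more for no
measurable difference in the intervals. The default is 10,000 iterations;
the test suite runs the same code path at a few hundred.

## The categorical classification-error index

As a model-free check, responses, targets and inducers are assigned to the
three prototype categories. A trial is a *classification error* when the
response category differs from the target category. Errors are partitioned
by the inducer's category; within each partition the fraction of errors
landing in the inducer's own category is computed, the three fractions are
averaged, expressed in percent, and the 33.33% chance baseline subtracted.
Positive values mean error responses are drawn toward the inducer's
category.

The *per-partition* denominator is used deliberately: under independence
of response and inducer, an error response is uniform over the two
non-target categories and the inducer's category is independent of it, so
each partition's expected fraction is exactly 1/3 — the stated baseline.
With a grand-total denominator the null value would depend on the error
mix across partitions, and no fixed baseline applies; that variant is kept
behind `denominator = "grand"` for sensitivity analysis only. Trials whose
inducer and target share a category are retained — such a trial can never
feed its own partition's numerator (an error response is by definition
outside the target's category), and the 1/3 null holds with them included,
which the Monte-Carlo null test verifies. A partition with zero errors has
an undefined ratio; the index then averages the defined partitions and
warns (inside `run_analysis()` the warning is routed to the run log).

Classification *accuracy* is the percent of trials whose response lands in
the target's category, with a dispersion reported as the SD of the
accuracy across bootstrap resamples (the reporting convention for these
accuracies does not pin down what the "±" is; the bootstrap SD is used and
labelled as such). Note that accuracy is computed on *filtered* trials:
because the ±60-step error filter removes the far tail, the chance floor
on kept trials is 47/121 ≈ 38.8%, not 33.3% — relevant when calibrating
the simulator to a target accuracy.

## The synthetic observer

Human data for this task are not publicly deposited, so every stage is
validated against a generative observer with known ground truth:

* **Design**: exact balanced schedules in pseudorandom order (Experiment
  1: each of the 20 cells 9 times per 180-trial session; Experiment 2:
  each of the 6 cells 50 times per 300-trial session), Face 1 and Face 2
  independent and uniform on the wheel.
* **Response**: target + DoG bias toward the inducer + wrapped Gaussian
  noise, rounded to the nearest wheel position. The generating bias is
  parameterised directly by its half-amplitude (converted internally to
  $\alpha$ via the closed form) so truth and estimate share units. The
  default amplitude map places attraction where the human experiments
  found it (3.6 and 5.9 steps in the two 1-s-ISI cells of Experiment 1;
  2.1 and 2.4 steps in the Face-2-target cells of Experiment 2) and zero
  elsewhere.
* **Noise**: a discrete wrapped Gaussian (a von Mises would serve equally;
  the wrapped Gaussian was chosen for its closed-form relation between sd
  and accuracy at small sd). The default `noise_sd = 16` steps was set
  once by `calibrate_noise()` to put classification accuracy at ~72%, the
  middle of the human range; the calibration is a bisection against the
  simulated accuracy with a fixed seed per evaluation.
* **Lapses**: with probability 0.05 the response is uniform on the wheel;
  half of those trials also draw a response time above 15 s, so both
  exclusion rules are exercised. Other trials draw lognormal response
  times with median 5 s. The resulting removal fraction (~3%) is close to
  the 2–4% reported for human sessions, and its expected value is a known
  function of the lapse rate, which the tests check.

What the simulator does **not** emulate: participant heterogeneity (one
observer model is shared), memory decay or any delay-dependence of noise,
across-trial carry-over (no bias from the previous trial by default), and
the perceptual similarity structure of real face morphs. Passing
parameter-recovery tests therefore shows the *estimator* is unbiased and
calibrated under the stated generative model — not that the model captures
every property of human data.

## Validation studies in the test suite

The acceptance tests run, at sizes chosen to keep a full check under
~15 minutes on one core (the code path is identical at any size):

1. exhaustive geometry oracle over all 141 × 141 position pairs;
2. closed-form half-amplitude agreement over a $(\sigma, \alpha)$ grid;
3. null calibration — 60 simulated null experiments of 1,800 trials
   (bootstrap CIs at 400 iterations): mean fitted half-amplitude within
   Monte-Carlo error of zero, CI significance rate inside the 60-replicate
   binomial band around the nominal 5%, and the categorical index within
   1 point of zero on 30,000 independent-uniform trials;
4. parameter recovery — planted half-amplitudes {0, 2, 4, 6} at 1,800
   trials: mean bias below 0.5 steps, from fit-only replicates whose
   counts (150/100/50/50) are allocated by the estimator's sampling SD at
   each amplitude, plus pooled 95% CI coverage in \[0.89, 1\] from 60
   bootstrap replicates;
5. pattern detection — 10 replicate experiments at the full 9,000-trial
   size with the default amplitude map: the planted cells must be
   significant in ≥ 90% of replicates and the 18 null cells fire at the
   nominal rate;
6. exact behaviour of the exclusion thresholds at their boundaries.

On detection power: at 9,000 trials, ~430 kept trials land in each of the
20 cells, and the bootstrap CI for a half-amplitude there has a width of
several morph steps — the same order as the CIs reported for human data at
this size. A planted amplitude near 3–4 steps is therefore close to the
detection limit of a single experiment of this size, and study 5 is the
empirical measurement of exactly that: it reports the per-cell detection
rate under the default (human-scale) effect sizes, rather than assuming
detection is easy.

## Reporting

`run_analysis()` composes everything: derive → filter → group → DoG fit +
bootstrap per condition and predictor variant → categorical index and
accuracy per condition, with non-estimable cells carried through, a
removal-fraction summary, and per-condition seeds derived deterministically
from one master seed so reruns are byte-identical. `moving_average()`
supplies the standard diagnostic overlay for fit plots (default window 15
morph steps — wide enough to smooth integer-step noise at ~450 trials per
condition, narrow enough to show the DoG peak); `plot()` on a fitted
`dog_fit` draws data, fit, and moving average together. No
multiple-comparison correction is applied across conditions by default,
matching the per-condition CI logic of the original analyses; users who
want one can apply `p.adjust`-style corrections to the significance table
themselves.

## Known limitations

* The bounds and multi-start grid of the constrained fit are declared
  package defaults; the constraint set used in the original MATLAB
  analyses of this task is not published, so exact numerical agreement
  with those fits is not claimed.
* The categorical index loses information relative to the continuous
  analysis by construction (three coarse bins), and its zero-error
  partition handling (average the defined partitions, warn) is a declared
  choice — reported small-sample indices should be read alongside
  `n_errors`.
* Near the detection floor the half-amplitude estimate is inflated: with
  $\sigma$ free down to 3 steps, a minority of fits on weak-signal data
  lock onto integer-step noise with a narrow, tall curve, which makes the
  estimator's sampling distribution heavy-tailed at amplitudes ≲ 2 steps
  and its mean bias there approach ~0.5 steps (the recovery study
  measures exactly this). Fixing `mu = 0` reduces, and raising the lower
  $\sigma$ bound would remove, this tail — both are available to users;
  the defaults keep the conventional, least-constrained fit.
* Pooling across participants treats trials as exchangeable; a clustered
  (participant-level) bootstrap is not currently implemented.
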