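---
title: "Evolving time-domain dyskinesia classifiers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving time-domain dyskinesia classifiers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caldera)
```

## The problem

Levodopa-induced dyskinesia — involuntary jerking and writhing movements —
is a common side effect of long-term dopamine replacement therapy in
Parkinson's disease. Clinicians titrate medication against it, but patients
are often unaware of their own dyskinesia and symptom diaries are
unreliable, so objective home monitoring from body-worn inertial sensors is
attractive. `caldera` implements a monitoring pipeline in which the
classifier itself is a symbolic mathematical expression, found by an
evolutionary algorithm, that operates directly on raw acceleration
magnitudes in the time domain. Working on raw data makes few assumptions
about what dyskinesia looks like, and time-domain expressions can
discriminate movements by their *shape* — important because the main
confounders (walking, some voluntary movements) occupy the same
low-frequency band as dyskinesia.

## The classifier model

A recording from a tri-axial accelerometer (100 Hz) is collapsed to a
univariate magnitude series, $m_i = \lVert (a_{x,i}, a_{y,i}, a_{z,i})
\rVert_2$, keeping gravity and sensor offsets: no filtering, detrending or
normalisation is applied. A window of 32 samples (0.32 s) slides along the
series one sample at a time, so a series of length $L$ yields $L - 31$
overlapping windows. The evolved expression $f$ maps each window to a
scalar, and the *segment score* is the mean of these values over all
windows — the mean occurrence of the movement pattern the expression
describes. Grading a segment (or an epoch of a day-long recording) is then
a matter of thresholding the score.

The expression is encoded as a Cartesian genetic programming (CGP) genome:
a $6 \times 6$ feed-forward grid of up to 36 function nodes drawn from
$\{+, -, \times, \div, \mathrm{mean}, \mathrm{min}, \mathrm{max},
\mathrm{abs}\}$, wired to 32 terminal inputs (the window samples). Each
node carries a function gene and two connection genes; a node may read any
terminal or any node in a strictly earlier column (unlimited levels-back).
Nodes not reachable from the output gene are inactive: they do not affect
the phenotype but are inherited and mutated, providing neutral genetic
variation. Design choices here that the genome layout forces or standard
CGP practice supplies: every function takes two connection genes with `abs`
ignoring its second; `mean` is the two-argument mean $(a+b)/2$; division is
protected, returning the numerator when $|b| < 10^{-6}$, which makes every
expression total over finite inputs. We use a positional CGP encoding with
uniform node-wise crossover; it searches the same space (same geometry,
function set and connectivity) as implicit-context variants built for
crossover friendliness, and keeps the representation transparent.

Two spectral baselines share the identical genome geometry so that the
search spaces are directly comparable. The *long-term* variant feeds the
expression 32 spectral densities — a Welch-averaged periodogram (segments
of 256 samples, 50% overlap, Hann taper) reduced to 32 equal-width bins
tiling 0–50 Hz, DC excluded — one vector per segment. The *short-term*
variant computes a periodogram per 32-sample window (zero-padded to 64
samples so that exactly 32 one-sided non-DC bins exist) and averages the
expression output over windows, exactly as in the time domain. The padding
scheme is a documented choice: a 32-sample window natively yields only 16
non-DC one-sided bins.

## Training by evolution

Fitness of a genome is the AUC of its segment scores discriminating
clinically significant dyskinesia (grade $\ge 3$ on the 0–4 scale used for
rating observed dyskinesia per body part) from no dyskinesia (grade 0).
Segments graded strictly between 0 and 3 are excluded from training:
mild-grade labels are clinically noisy, and classifiers train more robustly
without them. Because raters can disagree and grades are averaged, grades
are real-valued; the rule is applied literally, so 2.5 is excluded and 3.5
included.

The evolutionary algorithm is generational: tournament selection (size 4),
uniform node-wise crossover with probability 0.9, per-gene point mutation
at rate 0.02, and elitism of 1 (which makes the best-so-far fitness
history non-decreasing). Defaults are a population of 200 for 100
generations; every run is fully determined by its seed. Tournament
selection was chosen over fitness-proportionate selection because AUC
fitness spans a compressed range near the top of the scale, where
proportional selection loses its gradient. Because separate runs settle in
different local optima, deployment models are chosen by running the
evolution many times independently and keeping the genome with the highest
AUC on a held-out test split (`multi_run_select()`); the full per-run AUC
distribution is retained for box-plot comparisons between classifier
variants and data sources.

## Evaluation toolkit

AUC uses the Mann–Whitney rank formulation with ties counting one half;
it is invariant under monotone transforms of the score, and the
trapezoidal area under the swept ROC curve reproduces it to rounding
error. Confidence bands on the ROC are computed by stratified bootstrap
(resampling within class, 2.5/97.5 percentile TPR envelope on a fixed FPR
grid). Per-grade thresholds maximise Youden's $J$ (sensitivity +
specificity − 1) by an exhaustive sweep over cut-points, with ties
resolved to the lowest threshold and the resulting thresholds coerced
monotone across grade boundaries; Youden's criterion is our choice of
"optimal" — the underlying sensitivity/specificity trade-off is reported
alongside. Activity-stratified AUC tables flag, rather than score, strata
missing a class. For interpretation, `top_window_pattern()` averages the
windows the classifier scores highest; comparing that mean against a known
waveform uses `waveform_similarity()`, the correlation at the best
alignment within ±10 samples, because the expression's preferred phase for
a burst inside its 32-sample frame is arbitrary.

The clinical summary (`episode_summary()`) cuts a recording into
fixed-length epochs (60 s by default; the resolution is a reporting choice,
not a model constraint), scores each epoch, bands it with the calibrated
thresholds, and merges adjacent epochs in the same band at grade ≥ 3 into
episodes. No gap-bridging is applied: two high-grade epochs separated by a
lower epoch are two episodes. Sleep is a user-supplied annotation — the
package deliberately does not infer sleep from the signal — and sleep
epochs are excluded from banding; medication times are carried through as
chart annotations.

## The synthetic study generator

Clinical recordings of this kind are not redistributable, so the package
ships a seeded generator whose output exercises every pipeline stage with
known ground truth. It emulates, at desk scale, a two-study design:
disjoint train/test/holdout splits of 10 s segments, with the holdout
split generated at a higher sensor noise level (0.08 g vs 0.05 g) to stand
in for a different set of sensor modules.

The planted dyskinetic signature is the "caldera" burst: two rise-and-fall
lobes, the second strictly shorter than the first, with a dip notched into
the first lobe's top. It is defined as a smooth function of relative
position (so resampling preserves shape), spans 32 samples (0.32 s) by
default, and is superposed on its carrier along the instantaneous gravity
axis so the shape survives in the magnitude series. Burst rate and
amplitude rise with clinical grade — grade → (occurrences/min, peak g):
1 → (4, 0.3), 2 → (8, 0.6), 3 → (14, 1.0), 4 → (22, 1.5) — with timing
jitter and ±10% time-warp per occurrence. Only the monotonicity of this
mapping is relied upon by tests; the absolute values are declared,
config-overridable placeholders.

Grade-0 segments come in three classes. *Rest* is gravity plus sensor
noise. *Walking* is the designed confounder: a 1.8 Hz cadence fundamental
with two harmonics and a per-step heel-strike transient (a short
Gaussian-windowed ~9 Hz impact). The heel strikes matter: they give
walking the same high-frequency spectral footprint as the burst's short
second lobe, so walking and dyskinesia overlap across the whole band the
burst occupies and spectral features cannot separate them by band alone —
the property that makes the time-vs-spectral comparison meaningful.
*Voluntary movement* is smooth bell-enveloped oscillation bursts.

Two further realism choices are load-bearing. Each recording gets a random
accelerometer calibration bias (sd 0.05 g per axis), and every segment a
slow postural sway (up to 0.15 g, 0.1–0.4 Hz): together these give grade-0
segments genuine diversity in mean level and energy, so that gross signal
level cannot separate the classes and the planted *shape* is what a
successful classifier must find. Walking stride amplitude is drawn per
segment from 0.35–0.75 g so walking energy overlaps the energy added by
bursts. Gyroscope channels carry the carrier movements at full scale but
the planted pattern at half amplitude (half SNR) with their own bias, so
rotational data are by construction the harder source. A configurable
fraction (default 0.2) of dyskinetic segments get a ±0.5 grade shift to
emulate rater-averaged fractional labels and exercise the training filter.

What the generator does **not** emulate: biomechanically realistic gait or
dyskinesia kinematics, inter-patient variability, sensor drift or
non-stationary noise, and the clinical studies' class proportions. Passing
tests on this surrogate therefore show that the pipeline recovers a
planted, conserved low-frequency pattern under confounders of matched band
and energy — not that the classifier reaches any particular accuracy on
real patients.

## Numerical choices and degenerate inputs

* Protected division threshold $10^{-6}$; all primitives total and finite.
* AUC requires both classes non-empty and errors otherwise; constant
  scores give 0.5 by the tie convention.
* Welch segments are 256 samples (50% overlap); series shorter than 256
  (but ≥ 64) fall back to a single segment of their own length.
* Threshold search candidates are midpoints between consecutive distinct
  scores plus sentinels beyond the extremes; classification is
  `score >= threshold`.
* Series shorter than 32 samples, absent channel groups, non-finite
  samples, degenerate training sets, uncalibrated models and truncated
  model files all raise immediate, specific errors.
* Every stochastic step (genome draws, evolution, bootstrap, generator)
  runs off an explicit seed; `evolve()` and `generate_study()` restore the
  caller's RNG state.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the default study
(58/42/42 segments of 10 s across train/test/holdout) with 10 independent
evolutions at population 50 for 40 generations — a deliberate desk-scale
setting of the full procedure (population 200, 100 generations, 50 runs)
that keeps a complete training-selection-validation cycle in the order of
a minute on one CPU. The knobs scale directly: `evolution_config()` for
population/generations, the `counts` table of `synthetic_config()` for
study size, and the seed lists of `multi_run_select()` for the number of
runs.

## Known limitations

* The evolved expression is selected for ranking (AUC), not calibration;
  thresholds must be fitted afterwards on labelled scores.
* Per-sensor classification only: no fusion across body sites.
* Non-100 Hz recordings are rejected rather than resampled.
* Synthetic evidence only, as discussed above; the generator's per-grade
  rates and amplitudes are declared placeholders.
* Which window alignment an evolved classifier prefers is arbitrary, so
  recovered patterns are compared to templates phase-invariantly.
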