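---
title: "Estimating multi-DoF isometric hand force and torque from FMG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating multi-DoF isometric hand force and torque from FMG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmgstack)
```

## The problem

Force myography (FMG) reads the pressure pattern that contracting forearm
and upper-arm muscles produce at the skin surface, via arrays of
force-sensing resistors (FSRs) worn as bands. `fmgstack` implements an
analysis pipeline for estimating the six degrees of freedom of isometric
hand loading — forces $F_x, F_y, F_z$ (N) and wrist torques
$T_x, T_y, T_z$ (Nm) measured by a load cell — from 60 FSR channels in
four bands (12 at the wrist, 16 each at the forearm midway, the forearm
muscle belly, and the upper arm), sampled at 10 Hz.

The pipeline has five parts:

1. a **synthetic data generator** that emulates the acquisition protocol
   (5 trials x 7 sessions x 400 samples), so that every downstream stage
   is testable without access to human recordings;
2. **preprocessing**: causal high-pass detrending of the FMG channels,
   causal FIR low-pass smoothing of FMG and labels, and min-max
   normalization referenced to training data only;
3. **feature augmentation**: temporal derivatives, and (for the second
   stage) the spherical-coordinate transform of predicted force/torque
   triples;
4. **two-stage stacked regression**: per-axis GRNN, nu-SVR or
   random-forest models in stage 1, a single multi-output GRNN in stage 2;
5. **evaluation and inference**: per-axis $R^2$ under leave-one-trial-out
   validation, swept over all 15 band combinations, compared by two-way
   ANOVA (band combination x algorithm) with Tukey HSD post-hoc tests.

## Models

### GRNN

The general regression neural network is a Nadaraya-Watson kernel
regressor. Training memorizes the data (one pattern unit per training
sample); prediction is the Gaussian-weighted average

$$\hat Y(x) = \frac{\sum_i Y_i \exp\!\left(-D_i^2/2\sigma^2\right)}
                   {\sum_i \exp\!\left(-D_i^2/2\sigma^2\right)},
  \qquad D_i^2 = (x - X_i)^\top (x - X_i),$$

with a single spread parameter $\sigma$. Predictions are convex
combinations of training outputs, so every output lies within the
training range. A multi-output GRNN with shared $\sigma$ is exactly
equivalent to independent per-output GRNNs with that $\sigma$, which is
why one model serves all six axes. `grnn_predict()` subtracts the
row-wise maximum exponent before exponentiation, so the weight of the
nearest pattern unit is always 1 and the ratio never underflows to 0/0;
should that still happen, the nearest unit's output is returned. The
implementation is checked against a literal double-loop transcription of
the kernel average to $10^{-10}$ in the test suite.

### nu-SVR and random forest

Stage 1 alternatives are standard learners used per their published
definitions: nu-SVR with an RBF kernel
$k(x,y) = \exp(-\lVert x-y\rVert^2 / 2\sigma_{rbf}^2)$ via `e1071::svm()`
(one model per output axis), and random-forest regression — the ensemble
mean $f(x) = \tfrac1B \sum_b T_b(x)$ over $B$ trees — via
`randomForest::randomForest()` with seeded bootstrap randomness. The
package does not re-implement these solvers; its surface adds input
validation, the bandwidth convention above, and determinism contracts.

### Two-stage stacking

Stage 1 maps FMG features (normalized channels and their first
difference) to each axis separately. Stage 2 is a multi-output GRNN on
the concatenation

    raw FMG | d(FMG) | stage-1 predictions | d(predictions) | spherical(predictions)

trained against the same true labels, and its outputs are the reported
predictions. The spherical transform re-expresses each predicted triple
as radius, polar angle from +Z, and azimuth (`atan2`, radians; the
degenerate all-zero triple maps to zeros) — the motivation is that joint
load magnitude and direction are more directly related to muscle
recruitment than Cartesian components are. The rationale for a second
stage is the cross-axis structure of hand exertion: a subject aiming at
one axis consistently co-activates others, so the six true labels are
correlated and a joint model of the stage-1 predictions can exploit that
correlation.

Hyperparameters are grid-searched by k-fold cross-validated mean MSE
(averaged over folds and output dimensions), with ties broken toward the
smoother model (larger spread, larger RBF width then smaller cost, fewer
trees).

### Evaluation

Accuracy is the coefficient of determination of the final (stage-2)
predictions, computed per axis and held-out trial,

$$R^2 = 1 - \frac{\sum_n (\hat y(n) - y(n))^2}{\sum_n (y(n) - \bar y)^2},$$

retained unclamped (negative values count), then averaged over axes and
trials ("3-DoF" / "6-DoF" $R^2$). Validation is cross-trial: each trial
is held out once, with filter state, normalization statistics, tuned
hyperparameters and stage-2 training features all derived from the
remaining trials only. For balanced folds the axis-then-trial and
trial-then-axis averaging orders agree; `aggregate_results()` averages
the fold-level table in one step.

Band-placement and algorithm effects are tested on the per-subject mean
$R^2$ (one observation per subject x band combination x algorithm) by a
fixed-effects two-way ANOVA with interaction, followed by Tukey HSD
studentized-range pairwise comparisons at $\alpha = 0.05$.

## The synthetic data generator

No public FMG/load-cell corpus exists for this protocol, so
`generate_subject()` emulates it:

* **Focused sessions.** The focused axis is $A\sin(2\pi f t + \varphi)$
  with $f \sim U(0.05, 0.125)$ Hz (2–5 cycles per 40 s session, the
  cadence a subject tracking a slow visual target produces) and $A$ the
  nominal amplitude (20 N force, 2 Nm torque — a comfortable isometric
  hand exertion scale) jittered by ±10%. Every other axis receives a
  *leakage* copy of the focused waveform plus smooth noise, both scaled
  to the receiving axis' own range (at most ~30% and 10% of it,
  respectively). Leakage coefficients (magnitude $U(0.05, 0.30)$, random
  sign) are drawn **once per subject**: co-activation is a stable
  individual trait, and a fixed coupling is what makes the cross-axis
  structure learnable across trials — the property the second stage is
  designed to exploit.
* **Free sessions.** Each axis is independent zero-mean noise with
  spectral content at or below 0.4 Hz, scaled to 70% of the axis
  amplitude.
* **Sensor coupling.** Channel $j$ responds as
  $\text{baseline}_j + g_{trial}\,f(w_j \cdot y(t)/s) + \text{drift}_j t
  + \varepsilon$, clamped at zero (an FSR cannot read negative). The
  axis scale $s$ puts forces and torques on a common drive scale; $f$ is
  a softplus (monotone, saturating); $w_j$ is a nonnegative per-channel
  weight vector multiplied by the band's gain row. The default gain
  matrix encodes the anatomical prior that the forearm muscle belly
  (band 3) is informative for all six axes while the upper arm (band 4)
  carries essentially no torque information (its torque gains are 3% of
  band 3's); this ordering is *encoded, not emergent*, and is what the
  band-placement analyses are expected to recover. Per-trial gain
  ($g_{trial} \sim N(1, 0.05^2)$, band re-seating between trials),
  linear drift (SD $5\times10^{-5}$ per sample) and additive noise
  (SD 0.1, roughly 8% of the signal swing — wearable FSR contact and motion noise is substantial) are the defaults; all are
  configuration-exposed.

What the generator does **not** emulate: posture drift, muscle fatigue,
electromechanical sensor dynamics, rest periods between sessions, or any
musculoskeletal geometry. Passing tests on this family shows the pipeline
recovers structure the generator encodes; it does not certify accuracy
on human recordings.

## Numerical and study-design choices

Several choices were genuinely open; the package fixes them as follows.

* **Filters.** "5th order FIR" is read as 6 taps (order = taps − 1),
  Hamming-windowed, normalized to exact unit DC gain so label units are
  preserved. Filtering is causal (no zero-phase compensation; group
  delay ≤ 2.5 samples accepted) and applied per trial, never across
  trial boundaries. Both filters are warm-started at the steady state
  for the first sample held constant, so a sensor baseline produces no
  startup transient — for the first-order high-pass the initial-state
  correction is applied in closed form.
* **Detrending cutoff.** `filter_spec()` defaults to the published
  chain (first-order Butterworth high-pass at 0.5 Hz). On the synthetic
  family, however, *all* exertion energy lies at 0.05–0.125 Hz by
  construction, and a 0.5 Hz causal first-order high-pass attenuates
  that band to ~20% amplitude with a ~75° phase rotation, and cross-trial
  accuracy collapses. Real
  FMG retains force-tracking content after detrending (normalized FMG
  traces visibly follow the exerted sinusoid), so for the synthetic
  study this package places the detrending cutoff *below* the exertion
  band, at 0.02 Hz — it still removes offset and slow drift, which is
  the filter's purpose. All synthetic-study results in this vignette,
  the test suite and `scripts/acceptance.R` use
  `filter_spec(hp_cutoff_hz = 0.02)`; the sensitivity can be studied by
  varying `hp_cutoff_hz`.
* **Tuning folds.** `tuning_plan()` defaults to shuffled k-fold (common
  practice). On smooth, densely sampled trajectories shuffled folds
  place each validation sample next to its temporal neighbours'
  training copies, so cross-validation rewards memorization: the GRNN
  spread is driven to the grid minimum and cross-trial accuracy
  suffers. The synthetic study therefore tunes with *trial-blocked*
  folds (`fold_type = "blocked"`, one fold per training trial), which
  select larger spreads and measurably better cross-trial $R^2$.
* **Stage-2 training predictions.** In-sample stage-1 predictions (the
  default) follow the original two-stage diagram; a trial-wise
  cross-fitted variant (`stage2_train = "crossfit"`) is available. With
  2–4 training trials the cross-fitted out-of-fold models see a third
  to a half less data than the final stage-1 models, making the stage-2
  training features *pessimistically* noisy; measured on seeded
  cohorts, in-sample dominates. Cross-fitting is preferable only when
  stage 1 memorizes (see previous point).
* **Feature scaling.** Assembled feature matrices mix blocks of very
  different scales (normalized FMG in [0,1], first differences an order
  of magnitude smaller, predictions in N and Nm). Inside
  `fit_two_stage()` each assembled matrix is min-max normalized from
  training statistics so a single kernel bandwidth is meaningful across
  blocks; the normalizers are stored and re-applied at prediction.
* **Derivative convention.** First difference with a leading zero,
  computed within each trial.
* **Spherical angles** are radians; the convention is ISO physics
  (polar from +Z, azimuth `atan2(y, x)`).
* **Degenerate inputs.** Constant training channels normalize to 0 with
  a warning; constant SVR targets return the constant; constant
  responses give a flagged (NaN F) ANOVA; a constant true sequence is a
  labeled error for $R^2$.
* **Default grids.** GRNN spread: 10 log-spaced values in [0.01, 1]
  (features are min-max normalized); nu in {0.25, 0.5, 0.75}, cost in
  {1, 10, 100}, RBF width in {0.1, 1, 10}; 50/100/200 trees with node
  sizes 1/5/10. The study runs below use reduced grids, stated with
  each result.

## Problem sizes used in tests and the acceptance script

The full protocol (9 subjects x 5 trials x 14,000 samples, 15 band
combinations, 3 algorithms) is far larger than automated test runs
should be, so the seeded study cohorts use subjects with 3 trials of
15 s sessions (3,150 samples each), GRNN stage 1 with the spread grid
{0.05, 0.1, 0.2, 0.5}, and trial-blocked 2-fold tuning. The stacking
study uses 20 single-subject cohorts; the band-placement study ranks
cohort-mean accuracy over 10 cohorts of 2 subjects each (the
band-placement claim is about the subject-averaged comparison); the
noise-free SVR recovery study uses one subject with fixed
hyperparameters (nu 0.5, cost 10, RBF width 3 on normalized features).
Protocol arithmetic (sample counts, band sizes, combination counts) is
always checked at the full default scale, which costs nothing.

## Findings on the synthetic family, and known limitations

* **Band placement is recovered.** With the default coupling preset the
  muscle-belly band ranks first and the upper-arm band last among
  single bands in nearly all seeded cohorts, and the Tukey contrast
  between them is significant in the cohort ANOVA — the generator's
  encoded anatomy is recovered through the full pipeline.
* **More bands help.** The all-band configuration matches or beats the
  best single band, echoing the spatial-coverage effect.
* **The second stage helps when stage 1 is genuinely noisy.** At the
  default sensor noise the stage-2 multi-output GRNN gains on the
  order of +0.1 mean $R^2$ over stage 1 in the large majority of
  seeded cohorts (the test suite runs this as a 20-cohort sign test):
  with subject-stable cross-axis coupling, the six noisy per-axis
  predictions are jointly redundant, and the second stage exploits
  that redundancy. The gain is noise-dependent — in near-noise-free
  variants stage 1 is already close to the information ceiling and
  stage 2 merely tracks it, typically losing several hundredths of
  $R^2$ to kernel smoothing bias and the extra feature dimensions
  diluting kernel distances; for that reason a noise-free
  parameter-recovery check of the *final* two-stage output sits below
  what the stage-1 output alone achieves. With independent axes (zero
  leakage) the mean change stays well inside a 0.05 degradation
  bound.
* The ANOVA's factor tests are calibrated (null type-I error within
  [0.03, 0.07] at $\alpha = 0.05$ over simulated cohorts), and Tukey
  HSD p-values agree with a permutation oracle on toy designs.

## A worked example

```{r example, eval = FALSE}
library(fmgstack)

cfg <- protocol_config(n_trials = 3, session_duration_s = 20, seed = 1)
layout <- band_layout()
coupling <- coupling_model(layout, seed = 101)
subject <- generate_subject(cfg, coupling, layout, seed = 1)

study_spec <- filter_spec(hp_cutoff_hz = 0.02)
study_plan <- tuning_plan(grid = data.frame(sigma = c(0.05, 0.1, 0.2, 0.5)),
                          n_folds = 2, fold_type = "blocked", seed = 1,
                          grid_stage2 = data.frame(sigma = c(0.1, 0.3, 1)))

res <- cross_trial_evaluate(subject, case_config(2, stage1_algorithm = "grnn"),
                            band_combination(1:4), study_plan, study_spec)
aggregate_results(cbind(subject = "S1", case = 2L, target = "all",
                        combo = "1+2+3+4", algorithm = "grnn", res))
```
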