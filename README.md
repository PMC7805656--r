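# fmgstack

Two-stage stacked regression for estimating multi-degree-of-freedom
isometric hand force and torque from force myography (FMG).

## The problem

Force myography reads the pressure pattern that contracting arm muscles
produce at the skin surface, using bands of force-sensing resistors
(FSRs). Given 60 FSR channels in four bands (wrist, forearm midway,
forearm muscle belly, upper arm) sampled at 10 Hz, synchronized with a
6-DoF load cell (forces Fx, Fy, Fz in N; torques Tx, Ty, Tz in Nm), the
task is to estimate the six load components from the FMG alone, and to
ask which band placements matter. The intended audience is researchers in
wearable biosignal processing and rehabilitation engineering.

## The method

1. **Preprocessing**: causal 1st-order Butterworth high-pass detrending
   of the FMG channels, a 6-tap Hamming-windowed FIR low-pass (unit DC
   gain) on FMG and labels, and per-channel min-max normalization
   referenced to training data only.
2. **Stage 1**: one regressor per axis on the normalized channels plus
   their first difference — a GRNN (Nadaraya–Watson kernel average,

   ```
   yhat(x) = sum_i Y_i exp(-D_i^2 / 2 sigma^2) / sum_i exp(-D_i^2 / 2 sigma^2)
   ```

   implemented here from that definition), nu-SVR with an RBF kernel, or
   random-forest regression. Hyperparameters by k-fold grid search.
3. **Stage 2**: a single multi-output GRNN on
   `raw FMG | d(FMG) | stage-1 predictions | d(pred) | spherical(pred)`,
   exploiting cross-axis correlation of hand exertion.
4. **Evaluation**: per-axis R² = 1 − SSE/SST under leave-one-trial-out
   validation, swept over all 15 band combinations; band and algorithm
   effects compared by two-way ANOVA with Tukey HSD.

Because no public dataset exists for this protocol, the package ships a
protocol-structured synthetic generator (`generate_subject()`): sinusoidal
focused-axis sessions with subject-stable cross-axis leakage, a free
multi-axis session, and FMG channels as nonnegative nonlinear mixtures of
the six axes with baseline, drift, sensor noise and per-trial gain
variation. The band-gain structure encodes the anatomical prior that the
muscle-belly band is informative for all six axes while the upper-arm
band is blind to torque.

## Worked example

```r
library(fmgstack)

cfg      <- protocol_config(n_trials = 3, session_duration_s = 20, seed = 1)
layout   <- band_layout()
coupling <- coupling_model(layout, seed = 101)
subject  <- generate_subject(cfg, coupling, layout, seed = 1)

study_spec <- filter_spec(hp_cutoff_hz = 0.02)  # detrending below the exertion band
study_plan <- tuning_plan(grid = data.frame(sigma = c(0.05, 0.1, 0.2, 0.5)),
                          n_folds = 2, fold_type = "blocked", seed = 1,
                          grid_stage2 = data.frame(sigma = c(0.1, 0.3, 1)))

res <- cross_trial_evaluate(subject,
                            case_config(2, stage1_algorithm = "grnn"),
                            band_combination(1:4), study_plan, study_spec)
mean(res$r2_stage1); mean(res$r2)
```

On this seed the run prints

```
[1] 0.6334091
[1] 0.6347836
```

— the 6-DoF mean R² over the three held-out trials for the stage-1 GRNN
and the final stage-2 output (here the model explains ~63% of the
held-out load-cell variance; at the default sensor noise the second
stage improves on stage 1 in the large majority of seeded cohorts, see
the methods vignette, which also documents all study-protocol choices: the 0.02 Hz
detrending cutoff, trial-blocked tuning folds, and reduced problem
sizes). Restricting to single bands ranks the muscle-belly band first
and the upper-arm band last, recovering the encoded anatomy.

A thin command-line front end over the same functions is in
`inst/cli/fmgstack.R` (`simulate`, `run`, `sweep`, `report` subcommands).

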