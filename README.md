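# gaitmod

Tensor decomposition of locomotor modules from joint-angle and EMG data.

## The problem

When humans walk or run, many joints and muscles are coordinated through a
small number of *modules*: groups of channels (a spatial module `w_r`)
driven by a common activation waveform over the gait cycle (a temporal
module `p_r`). How strongly each module is recruited changes with the task —
here, locomotion at a given treadmill speed by a given subject. Classical
matrix decompositions (PCA, NNMF) of channel-by-time data can recover the
modules, but quantify task dependence only after the fact, for either the
spatial or the temporal side.

`gaitmod` instead fits a CANDECOMP/PARAFAC (CP) decomposition to a
three-way data tensor `X` (channels `S` x cycle frames `T` x tasks `K`):

    X[i,j,k] ≈ Σ_{r=1}^{R} λ_r · w[i,r] · p[j,r] · t[k,r],
    ‖w_r‖ = ‖p_r‖ = ‖t_r‖ = 1,  λ_r ≥ 0,

so every component couples a spatial module, a temporal module, **and** a
task-dependent modulation `t_r` that says how much that spatiotemporal
module is recruited in each (subject, speed) task — all estimated
simultaneously. Joint angles (signed) are fitted by alternating least
squares; EMG envelopes are fitted with non-negativity constraints
(`w, p, t ≥ 0`) by multiplicative updates. Per rank-`R` fit, CP estimates
`(S + T + K)·R` parameters, against `(S + T·K)·R` for the stacked matrix
factorization `Z ≈ Σ w_r p_rᵀ` and `S·T·K·R` for task-by-task matrix fits —
the parameter-count comparison the package reproduces exactly.

The number of components is the smallest `R` whose *variance accounted for*
(uncentered coefficient of determination, `1 − Σ(X−X̂)²/ΣX²`) strictly
exceeds a threshold (0.7 for group fits, 0.8 per subject). Walk-specific
and run-specific modules are identified from the discontinuity statistic
`|t(1.8 m/s) − t(2.3 m/s)|` per component, and recruitment differences
across muscles are tested with a two-factor (muscle x mode)
repeated-measures ANOVA followed by Tukey comparisons.

The package is for motor-control and biomechanics researchers who want this
pipeline as tested, reusable code. Because the original recordings are not
publicly deposited, a synthetic-data module generates tensors with planted
ground-truth factors (speed-linear, walk-specific, run-specific, constant
modulations; per-subject walk-run transitions in 1.9-2.3 m/s) so every
stage is verifiable end to end.

## What is in the box

- **Synthetic data**: `synthetic_spec()`, `generate_ground_truth()`,
  `synthesize_tensor()`, `synthesize_raw_recording()`.
- **Preprocessing**: `butterworth_zero_lag()`, `rectify_and_smooth()`,
  `detect_gait_events()`, `segment_cycles()`, `time_normalize()`,
  `standardize_joint_angles()`, `scale_emg()`, `bin_speeds()`,
  `assign_and_average()`, `assemble_tensor()`.
- **CP decomposition**: `cp_als()`, `cp_nonneg()`, `select_rank()`,
  `reconstruct()`, `fitting_error()` / `variance_explained()`,
  `normalize_components()`, `parameter_counts()`.
- **Matrix baselines**: `stack_tasks()`, `pca_modules()`, `nnmf_modules()`,
  `unstack_temporal()`.
- **Module analysis**: `mode_discontinuity()`, `match_components()`,
  `recovery_score()`, `rm_anova_two_way()`.
- **Pipeline & I/O**: `pipeline_config()`, `run_pipeline()`, plain-text
  tensor/model containers (`write_data_tensor()`, `write_cp_model()`),
  `tidy()`/`glance()` methods and `autoplot()`/`plot_rank_curve()` figures.

## Worked example

```r
library(gaitmod)

cfg <- pipeline_config(
  seed = 5,
  spec = list(kind = "emg", S = 8, T = 40, R = 3, n_subjects = 3,
              speed_min = 0.5, speed_max = 2.5, noise_sd = 0.6,
              profiles = c("speed_linear", "walk_specific", "run_specific")),
  R_max = 5, n_restarts = 2, max_iter = 150, tol = 1e-6
)
res <- run_pipeline(cfg)

res$selection$curve
#> # A tibble: 3 × 3
#>       R   vaf fitting_error
#>   <int> <dbl>         <dbl>
#> 1     1 0.386         0.614
#> 2     2 0.666         0.334
#> 3     3 0.862         0.138

res$contrast$components
#> # A tibble: 3 × 4
#>   component discontinuity dominance selected
#>       <int>         <dbl> <chr>     <lgl>
#> 1         1        0.0836 walk      TRUE
#> 2         2        0.0352 run       FALSE
#> 3         3        0.175  run       TRUE

round(res$recovery$score, 3)
#> [1] 0.994
```

Reading the output: the variance-accounted-for curve crosses the 0.7
threshold at `R = 3`, the planted number of components. Fitted components 3
and 1 have the largest walk-run discontinuities `|t(1.8) − t(2.3)|` and are
selected as the run-dominant and walk-dominant modules — matching them back
to the ground truth (`res$recovery$matches`) shows they are exactly the
planted run-specific and walk-specific components, while the planted
speed-linear component shows almost no discontinuity. The mean congruence
between fitted and planted factors is 0.994 — near-perfect recovery.

`autoplot(res$fit)` draws the standard module summary (bars = spatial,
lines = temporal, dots = task modulation, colored by walk/run);
`plot_rank_curve(res$selection)` draws the selection curve.

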