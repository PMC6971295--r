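Package: gaitmod
Title: Tensor Decomposition of Locomotor Modules from Joint-Angle and EMG Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts spatial modules, temporal modules, and task-dependent
    modulations from multichannel human locomotion recordings via
    CANDECOMP/PARAFAC (CP) tensor decomposition, either unconstrained
    (alternating least squares, for joint angles) or non-negative
    (multiplicative updates, for EMG envelopes). Includes the full
    preprocessing chain (zero-lag Butterworth filtering, gait-event
    detection from vertical ground-reaction force, cycle segmentation and
    200-frame time normalization, per-subject standardization and scaling,
    speed binning, tensor assembly), matrix-decomposition baselines (PCA and
    non-negative matrix factorization on the stacked channel-by-time-task
    matrix), model-order selection by variance accounted for, walk-run
    discontinuity statistics with component matching, a two-factor
    repeated-measures ANOVA with Tukey post hoc comparisons, and a synthetic
    data generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
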