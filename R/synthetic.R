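#' Specification for synthetic locomotion tensors with planted ground truth
#'
#' Describes a synthetic study from which ground-truth CP factors and noisy
#' data tensors are generated. Two presets mirror the two study designs the
#' package targets: `"emg"` (non-negative muscle envelopes, speeds binned at
#' 0.1 m/s per subject) and `"angles"` (signed joint angles at a fixed speed
#' grid shared by all subjects). Every field can be overridden.
#'
#' Each synthetic subject has a walk-to-run transition speed drawn uniformly
#' from `transition_range` (default 1.9-2.3 m/s); a task is labeled `walk`
#' exactly when its speed is below that subject's transition speed.
#'
#' Per-component task-modulation profiles:
#' \describe{
#'   \item{`speed_linear`}{recruitment increases linearly with speed,
#'     `0.25 * r + (speed - min)/(max - min)` for component `r` (the
#'     per-component baseline keeps several speed-linear task columns
#'     linearly independent, hence the planted model identifiable).}
#'   \item{`walk_specific`}{baseline 0.15 plus `discontinuity_size` on
#'     walking tasks only (a discontinuous drop at the transition).}
#'   \item{`run_specific`}{baseline 0.15 plus `discontinuity_size` on
#'     running tasks only.}
#'   \item{`constant`}{equal recruitment in every task.}
#' }
#' Raw profiles are unit-normalized into the task factor columns.
#'
#' @param kind `"emg"` or `"angles"` preset.
#' @param S number of channels (muscles or joint angles).
#' @param T number of time frames per normalized gait cycle.
#' @param R number of planted components.
#' @param n_subjects number of synthetic subjects.
#' @param speeds explicit speed grid (m/s) shared by all subjects, or `NULL`
#'   to use binned speeds.
#' @param speed_min,speed_max binned-speed range (m/s); `speed_max` may be a
#'   vector with one entry per subject (e.g. runners reaching higher speeds).
#' @param bin_width speed bin width (m/s).
#' @param noise_sd additive Gaussian noise SD, on the scale of a signal with
#'   unit root-mean-square (the planted weights are scaled so the noiseless
#'   tensor has RMS 1).
#' @param profiles character vector of length `R` of profile names; `NULL`
#'   for the preset default.
#' @param discontinuity_size size of the walk/run step in the raw profile.
#' @param nonneg generate a non-negativity-constrained model.
#' @param lambda_shape relative component weights before rescaling (length
#'   `R`; default equal).
#' @param transition_range interval the per-subject walk-to-run transition
#'   speed is drawn from.
#' @param temporal_width width (in cycle phase, 0-1) of the Gaussian bumps
#'   used as temporal modules.
#' @param seed master seed; all child seeds are derived from it.
#' @return A list of class `synthetic_spec`.
#' @export
#' @examples
#' synthetic_spec("emg", n_subjects = 4, speed_max = 2.5)
synthetic_spec <- function(kind = c("emg", "angles"),
                           S = NULL, T = 200L, R = NULL,
                           n_subjects = NULL,
                           speeds = NULL, speed_min = NULL, speed_max = NULL,
                           bin_width = 0.1,
                           noise_sd = NULL, profiles = NULL,
                           discontinuity_size = 1,
                           nonneg = NULL, lambda_shape = NULL,
                           transition_range = c(1.9, 2.3),
                           temporal_width = 0.05,
                           seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "emg") {
    if (is.null(S)) S <- 16L
    if (is.null(R)) R <- 6L
    if (is.null(n_subjects)) n_subjects <- 16L
    if (is.null(nonneg)) nonneg <- TRUE
    if (is.null(noise_sd)) noise_sd <- 0.95
    if (is.null(speeds) && is.null(speed_min)) {
      speed_min <- 0.3
      if (is.null(speed_max)) {
        speed_max <- rep(c(4.3, 5.0), each = ceiling(n_subjects / 2))[
          seq_len(n_subjects)
        ]
      }
    }
    if (is.null(profiles)) {
      profiles <- rep(c(
        "speed_linear", "run_specific", "speed_linear",
        "speed_linear", "constant", "walk_specific"
      ), length.out = R)
    }
  } else {
    if (is.null(S)) S <- 6L
    if (is.null(R)) R <- 3L
    if (is.null(n_subjects)) n_subjects <- 15L
    if (is.null(nonneg)) nonneg <- FALSE
    if (is.null(noise_sd)) noise_sd <- 0.3
    if (is.null(speeds) && is.null(speed_min)) {
      speeds <- c(
        0.56, 0.83, 1.11, 1.39, 1.67, 1.94, # instructed walking
        2.22, 2.50, 2.78, 3.06, 3.33 # instructed running
      )
    }
    if (is.null(profiles)) {
      profiles <- rep(
        c("speed_linear", "run_specific", "walk_specific"),
        length.out = R
      )
    }
  }
  if (is.null(speed_max)) speed_max <- NA_real_
  if (!is.null(speed_min)) speed_max <- rep(speed_max, length.out = n_subjects)
  spec <- structure(list(
    kind = kind, S = as.integer(S), T = as.integer(T), R = as.integer(R),
    n_subjects = as.integer(n_subjects),
    speeds = speeds, speed_min = speed_min, speed_max = speed_max,
    bin_width = bin_width,
    noise_sd = noise_sd, profiles = profiles,
    discontinuity_size = discontinuity_size,
    nonneg = isTRUE(nonneg), lambda_shape = lambda_shape,
    transition_range = transition_range,
    temporal_width = temporal_width,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  with(spec, {
    if (S < 1 || T < 2 || R < 1 || n_subjects < 1) {
      stop("synthetic spec dimensions must be positive (T >= 2)",
        call. = FALSE
      )
    }
    if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
    if (length(profiles) != R) {
      stop("`profiles` must have one entry per component", call. = FALSE)
    }
    bad <- setdiff(profiles, c(
      "speed_linear", "walk_specific", "run_specific", "constant"
    ))
    if (length(bad)) stop("unknown profile: ", bad[1], call. = FALSE)
    if (is.null(speeds)) {
      if (is.null(speed_min) || any(is.na(speed_max))) {
        stop("either `speeds` or `speed_min`/`speed_max` required",
          call. = FALSE
        )
      }
      if (any(speed_max <= speed_min) || bin_width <= 0) {
        stop("speed_max must exceed speed_min and bin_width > 0",
          call. = FALSE
        )
      }
    }
    if (length(transition_range) != 2 ||
        transition_range[2] < transition_range[1]) {
      stop("transition_range must be an interval", call. = FALSE)
    }
    invisible(NULL)
  })
}

#' Task grid of a synthetic spec
#'
#' Enumerates the `K` tasks (subject-major, speed ascending) with their
#' speeds, speed bins (binned designs) and walk/run modes. Modes follow each
#' subject's transition speed, drawn uniformly from the spec's
#' `transition_range` with a seed derived from the master seed.
#'
#' @param spec a [synthetic_spec()].
#' @return A tibble with columns `subject`, `speed`, `mode`, `transition`
#'   and, for binned designs, `speed_bin`, `speed_lo`, `speed_hi`.
#' @export
task_grid <- function(spec) {
  set.seed(spec$seed + 1L)
  transition <- stats::runif(
    spec$n_subjects, spec$transition_range[1], spec$transition_range[2]
  )
  rows <- lapply(seq_len(spec$n_subjects), function(s) {
    if (is.null(spec$speeds)) {
      bins <- bin_speeds(spec$speed_min, spec$speed_max[s], spec$bin_width)
      tibble::tibble(
        subject = s, speed = bins$mid, speed_bin = bins$bin,
        speed_lo = bins$lo, speed_hi = bins$hi,
        mode = ifelse(bins$mid < transition[s], "walk", "run"),
        transition = transition[s]
      )
    } else {
      tibble::tibble(
        subject = s, speed = spec$speeds,
        mode = ifelse(spec$speeds < transition[s], "walk", "run"),
        transition = transition[s]
      )
    }
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$subject, .data$speed)
}

# Raw (pre-normalization) task-modulation profile of component r. The
# speed_linear baseline grows with the component index so that several
# speed-linear components keep linearly independent task columns (a shared
# task column would make the planted CP model non-identifiable).
profile_raw <- function(profile, tasks, d, r = 1L) {
  switch(profile,
    constant = rep(1, nrow(tasks)),
    speed_linear = {
      rng <- range(tasks$speed)
      span <- if (diff(rng) > 0) diff(rng) else 1
      0.25 * r + (tasks$speed - rng[1]) / span
    },
    walk_specific = 0.15 + d * (tasks$mode == "walk"),
    run_specific = 0.15 + d * (tasks$mode == "run"),
    stop("unknown profile: ", profile, call. = FALSE)
  )
}

unit_norm <- function(v) {
  n <- sqrt(sum(v^2))
  if (n > 0) v / n else v
}

# Draw factor columns until pairwise |cosine| stays below `max_cos`; for
# non-negative factors each component activates a sparse channel subset so
# components do not collapse onto the shared all-positive direction.
draw_spatial <- function(S, R, nonneg, seed, max_cos = NULL) {
  set.seed(seed)
  if (is.null(max_cos)) max_cos <- if (nonneg) 0.35 else 0.7
  W <- matrix(0, S, R)
  for (r in seq_len(R)) {
    for (try in 1:200) {
      if (nonneg) {
        n_active <- max(2L, round(S / 4))
        w <- numeric(S)
        w[sample.int(S, n_active)] <- stats::runif(n_active, 0.3, 1)
      } else {
        w <- stats::rnorm(S)
      }
      w <- unit_norm(w)
      ok <- r == 1 ||
        max(abs(crossprod(W[, seq_len(r - 1), drop = FALSE], w))) < max_cos
      if (ok) break
    }
    W[, r] <- w
  }
  W
}

#' Generate planted ground-truth CP factors
#'
#' Builds a `ground_truth` model from a [synthetic_spec()]: spatial modules
#' as sparse (non-negative) or Gaussian (signed) channel weightings with
#' bounded pairwise overlap; temporal modules as smooth Gaussian bumps at
#' evenly spaced phases of the 200-frame cycle; task modulations from the
#' declared profiles, including discontinuous walk/run steps. All factor
#' columns are unit-norm; the weights `lambda` carry all scale and are
#' rescaled so the noiseless tensor has unit root-mean-square, which makes
#' `noise_sd` directly interpretable as a noise-to-signal amplitude.
#'
#' @param spec a [synthetic_spec()].
#' @return A `ground_truth` object (a [cp_model()] with the spec, profile
#'   labels and task grid attached). Deterministic given `spec$seed`.
#' @export
generate_ground_truth <- function(spec) {
  validate_synthetic_spec(spec)
  tasks <- task_grid(spec)
  K <- nrow(tasks)
  S <- spec$S; T <- spec$T; R <- spec$R

  spatial <- draw_spatial(S, R, spec$nonneg, seed = spec$seed + 2L)

  phase <- (seq_len(T) - 0.5) / T
  centers <- (seq_len(R) - 0.5) / R
  temporal <- vapply(seq_len(R), function(r) {
    unit_norm(exp(-(phase - centers[r])^2 / (2 * spec$temporal_width^2)))
  }, numeric(T))

  task <- vapply(seq_len(R), function(r) {
    unit_norm(profile_raw(spec$profiles[r], tasks, spec$discontinuity_size, r))
  }, numeric(K))

  shape <- if (is.null(spec$lambda_shape)) rep(1, R) else spec$lambda_shape
  if (length(shape) != R || any(shape <= 0)) {
    stop("lambda_shape must be R positive values", call. = FALSE)
  }
  # scale lambda so the noiseless tensor has unit RMS (||Xhat||^2 = S*T*K)
  G <- crossprod(spatial) * crossprod(temporal) * crossprod(task)
  e2 <- drop(crossprod(shape, G %*% shape))
  lambda <- shape * sqrt(S * T * K / e2)

  ord <- order(lambda, decreasing = TRUE)
  m <- cp_model(
    lambda[ord],
    spatial[, ord, drop = FALSE],
    temporal[, ord, drop = FALSE],
    task[, ord, drop = FALSE],
    nonneg = spec$nonneg, normalize = FALSE,
    channels = paste0("ch", seq_len(S)), tasks = tasks
  )
  # canonicalize signs the same way fitted models are canonicalized, so
  # recovery scoring compares like with like (order is already by lambda,
  # descending, and the stable sort leaves it unchanged)
  m <- normalize_components(m)
  m$profiles <- spec$profiles[ord][m$component_order]
  m$spec <- spec
  class(m) <- c("ground_truth", class(m))
  m
}

#' Synthesize a noisy data tensor from a planted model
#'
#' Adds iid Gaussian noise to the exact CP reconstruction of a ground-truth
#' model. For non-negative models the noisy tensor is clipped at zero
#' (additive-Gaussian-then-clip noise model); the pre-clip noise array is
#' stored in the `"noise"` attribute so tests can verify realized noise
#' levels exactly.
#'
#' @param truth a `ground_truth` model from [generate_ground_truth()].
#' @param noise_sd noise standard deviation; defaults to the spec's value.
#' @param seed seed for the noise draw (default derived from the spec seed).
#' @return A [data_tensor()] carrying the task grid, with attributes
#'   `noise` (pre-clip noise array) and `clipped` (count of clipped entries).
#'   With `noise_sd = 0` the tensor equals the exact reconstruction.
#' @export
synthesize_tensor <- function(truth, noise_sd = NULL, seed = NULL) {
  stopifnot(inherits(truth, "cp_model"))
  if (is.null(noise_sd)) noise_sd <- truth$spec$noise_sd
  if (is.null(seed)) seed <- truth$spec$seed + 3L
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  xhat <- as_plain_array(reconstruct(truth))
  d <- dim(xhat)
  if (noise_sd > 0) {
    set.seed(seed)
    noise <- array(stats::rnorm(prod(d), sd = noise_sd), dim = d)
  } else {
    noise <- array(0, dim = d)
  }
  x <- xhat + noise
  clipped <- 0L
  if (truth$nonneg) {
    clipped <- sum(x < 0)
    x <- pmax(x, 0)
  }
  dt <- data_tensor(x,
    channels = truth$channels, tasks = truth$tasks,
    nonneg = truth$nonneg
  )
  attr(dt, "noise") <- noise
  attr(dt, "clipped") <- clipped
  dt
}

#' Synthesize a continuous multichannel recording with ground-truth events
#'
#' Emulates a treadmill recording: per-cycle channel templates resampled to
#' variable cycle durations, plus a vertical ground-reaction-force channel
#' that is zero during swing and a half-sine pulse during stance. Cycles are
#' anchored at right-foot toe-off (the cycle starts in swing); foot contact
#' occurs `1 - duty` of the way through each cycle and stance runs to the
#' next toe-off. The true contact and toe-off sample indices are returned so
#' event detection and segmentation can be scored exactly.
#'
#' @param n_cycles number of gait cycles (>= 1).
#' @param fs sampling rate (Hz).
#' @param cycle_duration_s cycle duration(s) in seconds; scalar or length
#'   `n_cycles`.
#' @param templates `S x P` matrix of per-channel waveforms sampled on a
#'   uniform cycle-phase grid; default two smooth sinusoidal channels.
#' @param duty stance fraction of the cycle, in (0, 1).
#' @param grf_peak peak vertical GRF (N).
#' @param noise_sd additive Gaussian noise SD on the signal channels.
#' @param seed seed for the noise draw.
#' @return A list of class `motion_recording`: `signals` (`S x N`), `grf_z`
#'   (length `N`), `fs`, and ground-truth `events` ([gait_events()]) plus
#'   `cycle_starts` and `durations`.
#' @export
synthesize_raw_recording <- function(n_cycles, fs = 100,
                                     cycle_duration_s = 1.1,
                                     templates = NULL, duty = 0.6,
                                     grf_peak = 800, noise_sd = 0,
                                     seed = 1L) {
  if (n_cycles < 1) stop("at least one cycle required", call. = FALSE)
  stopifnot(fs > 0, duty > 0, duty < 1)
  durs <- rep(cycle_duration_s, length.out = n_cycles)
  if (any(durs <= 0)) stop("cycle durations must be positive", call. = FALSE)
  if (is.null(templates)) {
    ph <- seq(0, 1, length.out = 101)
    templates <- rbind(
      20 * sin(2 * pi * ph) + 5 * sin(4 * pi * ph),
      10 * cos(2 * pi * ph) - 3
    )
  }
  S <- nrow(templates)
  P <- ncol(templates)
  n_per <- pmax(round(durs * fs), 4L)
  tail_pad <- max(4L, round(0.05 * fs)) # trailing swing so the last
  N <- sum(n_per) + tail_pad # toe-off crossing is observable
  signals <- matrix(0, S, N)
  grf <- numeric(N)
  contacts <- integer(n_cycles)
  toe_offs <- integer(n_cycles)
  starts <- integer(n_cycles)
  pos <- 1L
  tpl_phase <- seq(0, 1, length.out = P)
  for (c in seq_len(n_cycles)) {
    n <- n_per[c]
    idx <- pos:(pos + n - 1L)
    ph <- seq(0, 1, length.out = n)
    for (s in seq_len(S)) {
      signals[s, idx] <- stats::approx(tpl_phase, templates[s, ], xout = ph)$y
    }
    contact_off <- round((1 - duty) * n)
    contacts[c] <- pos + contact_off
    starts[c] <- pos
    stance_len <- n - contact_off
    stance_ph <- (seq_len(stance_len) - 0.5) / stance_len
    grf[(pos + contact_off):(pos + n - 1L)] <- grf_peak * sin(pi * stance_ph)
    toe_offs[c] <- pos + n # first unloaded sample after stance
    pos <- pos + n
  }
  idx <- pos:N # trailing swing repeats the template start
  for (s in seq_len(S)) signals[s, idx] <- templates[s, 1]
  if (noise_sd > 0) {
    set.seed(seed)
    signals <- signals + matrix(stats::rnorm(S * N, sd = noise_sd), S, N)
  }
  structure(list(
    signals = signals, grf_z = grf, fs = fs,
    events = gait_events(contacts, toe_offs),
    cycle_starts = starts, durations = durs, templates = templates
  ), class = "motion_recording")
}
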