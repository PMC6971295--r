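#' Zero-lag Butterworth filtering
#'
#' Applies a Butterworth filter forward and backward (zero net phase shift),
#' the standard way kinematic and GRF signals are conditioned (4th order,
#' 15 Hz low-pass) and raw EMG is band-passed (20-450 Hz). Edge transients
#' are suppressed by removing the signal mean and padding with odd-symmetric
#' reflections before the forward-backward pass; output length equals input
#' length. The effective magnitude response is the squared Butterworth
#' magnitude `|H(f)|^2`.
#'
#' @param x numeric vector, or a channels-by-samples matrix filtered row-wise.
#' @param cutoff_hz cutoff frequency in Hz; for `band = "pass"` a length-2
#'   vector `c(low, high)`. Must lie strictly below the Nyquist frequency.
#' @param fs sampling rate (Hz).
#' @param order filter order (per pass).
#' @param band `"low"`, `"high"` or `"pass"`.
#' @return Filtered signal, same shape as `x`.
#' @export
butterworth_zero_lag <- function(x, cutoff_hz, fs, order = 4L,
                                 band = c("low", "high", "pass")) {
  band <- match.arg(band)
  if (is.matrix(x)) {
    return(t(apply(x, 1, butterworth_zero_lag,
      cutoff_hz = cutoff_hz, fs = fs, order = order, band = band
    )))
  }
  nyq <- fs / 2
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= nyq)) {
    stop("cutoff must lie in (0, fs/2)", call. = FALSE)
  }
  if (band == "pass" && length(cutoff_hz) != 2) {
    stop("band-pass needs cutoff_hz = c(low, high)", call. = FALSE)
  }
  n <- length(x)
  nmin <- 3L * (2L * order + 1L)
  if (n <= nmin) {
    stop("signal too short for filter warm-up (need > ", nmin, " samples)",
      call. = FALSE
    )
  }
  # pad long enough for the start-up transient of the lowest pole to decay
  npad <- min(n - 1L, max(nmin, ceiling(8 * fs / min(cutoff_hz))))
  bf <- signal::butter(order, sort(cutoff_hz) / nyq, type = band)
  mu <- mean(x)
  xc <- x - mu
  # odd reflection about the end points (MATLAB filtfilt-style padding)
  pre <- 2 * xc[1] - xc[(npad + 1):2]
  post <- 2 * xc[n] - xc[(n - 1):(n - npad)]
  y <- signal::filtfilt(bf, c(pre, xc, post))
  y <- y[(npad + 1):(npad + n)]
  if (band == "low") y + mu else y
}

#' Full-wave rectify and smooth an EMG signal into an envelope
#'
#' Takes band-passed raw EMG, full-wave rectifies it and low-pass filters
#' the rectified signal with a zero-lag Butterworth filter to obtain the
#' activation envelope. Zero-lag filtering of a non-negative signal can ring
#' slightly below zero, so the envelope is clipped at 0.
#'
#' @param emg_raw numeric vector or channels-by-samples matrix.
#' @param fs sampling rate (Hz).
#' @param smoothing_cutoff_hz envelope low-pass cutoff (default 4 Hz).
#' @param order filter order.
#' @return Non-negative envelope, same shape as the input.
#' @export
rectify_and_smooth <- function(emg_raw, fs, smoothing_cutoff_hz = 4,
                               order = 4L) {
  env <- butterworth_zero_lag(abs(emg_raw), smoothing_cutoff_hz, fs,
    order = order, band = "low"
  )
  pmax(env, 0)
}

#' Gait events
#'
#' Foot-contact and toe-off sample indices determined from the vertical
#' ground-reaction force on a stride-by-stride basis. Both series must be
#' strictly increasing, and merged in time they must alternate
#' contact/toe-off.
#'
#' @param contacts,toe_offs integer sample indices.
#' @return A list of class `gait_events`.
#' @export
gait_events <- function(contacts = integer(0), toe_offs = integer(0)) {
  contacts <- as.integer(contacts)
  toe_offs <- as.integer(toe_offs)
  if (is.unsorted(contacts, strictly = TRUE) ||
      is.unsorted(toe_offs, strictly = TRUE)) {
    stop("event indices must be strictly increasing", call. = FALSE)
  }
  if (length(contacts) && length(toe_offs)) {
    ev <- rbind(
      data.frame(i = contacts, type = "contact"),
      data.frame(i = toe_offs, type = "toe_off")
    )
    ev <- ev[order(ev$i), ]
    if (any(ev$type[-1] == ev$type[-nrow(ev)])) {
      stop("contacts and toe-offs must alternate", call. = FALSE)
    }
  }
  structure(list(contacts = contacts, toe_offs = toe_offs),
    class = "gait_events"
  )
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf(
    "<gait_events> %d contacts, %d toe-offs\n",
    length(x$contacts), length(x$toe_offs)
  ))
  invisible(x)
}

#' Detect gait events from the vertical ground-reaction force
#'
#' Thresholds the (already low-pass filtered) vertical GRF: a foot contact
#' is an upward crossing of the threshold and a toe-off is a downward
#' crossing (the index of the first sample at or below threshold). Loaded or
#' unloaded phases shorter than `min_phase_ms` are treated as noise and
#' merged into their neighbours before crossings are extracted.
#'
#' @param grf_z numeric vector of vertical GRF (N).
#' @param fs sampling rate (Hz).
#' @param threshold_n force threshold (N); default 20 N.
#' @param min_phase_ms minimum stance/swing phase duration (ms) retained;
#'   0 disables debouncing.
#' @return A [gait_events()]; empty (with a warning) when the signal never
#'   crosses the threshold.
#' @export
detect_gait_events <- function(grf_z, fs, threshold_n = 20,
                               min_phase_ms = 50) {
  above <- grf_z > threshold_n
  min_len <- max(1L, round(min_phase_ms / 1000 * fs))
  if (min_len > 1L && length(above)) {
    r <- rle(above)
    # short loaded blips first, then short unloaded gaps
    r$values[r$lengths < min_len & r$values] <- FALSE
    r <- rle(inverse.rle(r))
    inner <- seq_along(r$values)[-c(1, length(r$values))]
    r$values[inner][r$lengths[inner] < min_len & !r$values[inner]] <- TRUE
    above <- inverse.rle(r)
  }
  n <- length(above)
  if (!any(above)) {
    warning("no threshold crossings in GRF signal", call. = FALSE)
    return(gait_events())
  }
  contacts <- which(above & !c(FALSE, above[-n]))
  toe_offs <- which(!above & c(FALSE, above[-n]))
  # drop an initial toe-off / trailing contact so the series alternate
  if (length(toe_offs) && length(contacts) && toe_offs[1] < contacts[1]) {
    toe_offs <- toe_offs[-1]
  }
  if (length(contacts) > length(toe_offs)) {
    contacts <- contacts[seq_along(toe_offs)]
  }
  gait_events(contacts, toe_offs)
}

#' Segment a recording into gait cycles
#'
#' Cuts the signal channels into cycles between successive anchoring events
#' of the same foot. The default anchor is toe-off, matching the convention
#' that the cycle starts when the foot leaves the ground and ends when it
#' leaves again (frame 1 = toe-off, frame T = the return); contact anchoring
#' is available.
#'
#' @param recording a `motion_recording` (or a channels-by-samples matrix).
#' @param events a [gait_events()]; defaults to the recording's own events.
#' @param anchor `"toe_off"` or `"contact"`.
#' @return A list of cycles, each a list with `values` (channels x samples)
#'   and `duration_s`.
#' @export
segment_cycles <- function(recording, events = NULL,
                           anchor = c("toe_off", "contact")) {
  anchor <- match.arg(anchor)
  if (inherits(recording, "motion_recording")) {
    signals <- recording$signals
    fs <- recording$fs
    if (is.null(events)) events <- recording$events
  } else {
    signals <- as.matrix(recording)
    fs <- NA_real_
  }
  if (is.null(events)) stop("`events` required", call. = FALSE)
  a <- if (anchor == "toe_off") events$toe_offs else events$contacts
  if (length(a) < 2) {
    stop("need at least 2 anchoring events for one complete cycle",
      call. = FALSE
    )
  }
  lapply(seq_len(length(a) - 1L), function(i) {
    idx <- a[i]:(a[i + 1] - 1L)
    list(
      values = signals[, idx, drop = FALSE],
      duration_s = length(idx) / fs
    )
  })
}

#' Time-normalize a cycle to a fixed number of frames
#'
#' Resamples each channel of a variable-length cycle onto `n_frames` points
#' spanning the full cycle (both endpoints included) by linear
#' interpolation, so cycles of different durations and speeds become
#' comparable. Exact on linear signals; constant channels stay constant.
#'
#' @param cycle a channels-by-samples matrix (or a cycle list from
#'   [segment_cycles()]).
#' @param n_frames output frame count (default 200).
#' @return A channels-by-`n_frames` matrix.
#' @export
time_normalize <- function(cycle, n_frames = 200L) {
  values <- if (is.list(cycle)) cycle$values else as.matrix(cycle)
  L <- ncol(values)
  if (L < 2) stop("cycle must have at least 2 samples", call. = FALSE)
  xin <- seq(0, 1, length.out = L)
  xout <- seq(0, 1, length.out = n_frames)
  t(apply(values, 1, function(ch) stats::approx(xin, ch, xout = xout)$y))
}

#' Assemble a table of per-task cycle matrices
#'
#' The tabular intermediate between segmentation and the tensor: one row per
#' (subject, speed) with the time-normalized channels-by-frames matrix in a
#' list column. All per-subject normalization steps and the tensor assembly
#' operate on this table.
#'
#' @param values list of channels-by-frames matrices.
#' @param subject,speed,mode per-row descriptors.
#' @return A tibble with columns `subject`, `speed`, `mode`, `values`.
#' @export
cycle_table <- function(values, subject, speed, mode) {
  tibble::tibble(
    subject = subject, speed = speed, mode = mode, values = values
  )
}

check_cycle_table <- function(tbl) {
  stopifnot(all(c("subject", "speed", "values") %in% names(tbl)))
  dims <- vapply(tbl$values, dim, integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1) {
    stop("all cycle matrices must share the same dimensions", call. = FALSE)
  }
  invisible(dims[, 1])
}

#' Standardize joint angles per subject and channel
#'
#' Rescales every (subject, angle) series so that, pooled across all of that
#' subject's speeds and frames, the mean is 0 and the standard deviation
#' is 1. This makes different joints, speeds and subjects comparable before
#' tensor assembly. Idempotent; errors on a zero-variance channel, naming it.
#'
#' @param tbl a [cycle_table()] of per-task averaged cycles.
#' @return The table with standardized `values` matrices.
#' @export
standardize_joint_angles <- function(tbl) {
  check_cycle_table(tbl)
  denom_sd <- function(v) sqrt(sum((v - mean(v))^2) / length(v))
  for (s in unique(tbl$subject)) {
    i <- which(tbl$subject == s)
    pooled <- do.call(cbind, tbl$values[i]) # channels x (frames*speeds)
    mu <- rowMeans(pooled)
    sd_ <- apply(pooled, 1, denom_sd)
    if (any(sd_ == 0)) {
      ch <- which(sd_ == 0)[1]
      nm <- rownames(pooled)[ch]
      stop(sprintf(
        "zero-variance channel %s for subject %s",
        if (is.null(nm)) ch else nm, s
      ), call. = FALSE)
    }
    tbl$values[i] <- lapply(tbl$values[i], function(v) (v - mu) / sd_)
  }
  tbl
}

#' Scale EMG envelopes per subject and muscle
#'
#' Rescales every (subject, muscle) series so its maximum across all of that
#' subject's speeds and frames equals 1; zeros stay zero. Requires
#' non-negative input; errors on an all-zero muscle, naming it. Idempotent.
#'
#' @param tbl a [cycle_table()] of per-task averaged envelopes.
#' @return The table with scaled `values` matrices.
#' @export
scale_emg <- function(tbl) {
  check_cycle_table(tbl)
  for (s in unique(tbl$subject)) {
    i <- which(tbl$subject == s)
    pooled <- do.call(cbind, tbl$values[i])
    if (any(pooled < 0)) {
      stop("EMG scaling requires non-negative values", call. = FALSE)
    }
    mx <- apply(pooled, 1, max)
    if (any(mx == 0)) {
      ch <- which(mx == 0)[1]
      nm <- rownames(pooled)[ch]
      stop(sprintf(
        "all-zero muscle %s for subject %s",
        if (is.null(nm)) ch else nm, s
      ), call. = FALSE)
    }
    tbl$values[i] <- lapply(tbl$values[i], function(v) v / mx)
  }
  tbl
}

#' Half-open speed bins
#'
#' Divides `[speed_min, speed_max)` into left-closed, right-open bins of
#' `width` m/s (e.g. 0.3-0.4, 0.4-0.5, ...). A speed exactly at `speed_max`
#' falls outside the last bin.
#'
#' @param speed_min,speed_max range in m/s.
#' @param width bin width in m/s (default 0.1).
#' @return A tibble with columns `bin`, `lo`, `hi`, `mid`.
#' @export
#' @examples
#' nrow(bin_speeds(0.3, 4.3)) # 40
#' nrow(bin_speeds(0.3, 5.0)) # 47
bin_speeds <- function(speed_min, speed_max, width = 0.1) {
  stopifnot(speed_max > speed_min, width > 0)
  n <- round((speed_max - speed_min) / width)
  lo <- speed_min + (seq_len(n) - 1) * width
  tibble::tibble(bin = seq_len(n), lo = lo, hi = lo + width, mid = lo + width / 2)
}

#' Assign cycles to speed bins and average within each bin
#'
#' Assigns each cycle to the half-open bin containing its speed and replaces
#' the cycles of each (subject, bin) with their frame-wise arithmetic mean.
#' Bins that receive no cycles for a subject become missing tasks and are
#' reported with a warning; cycles outside the binning range are dropped
#' with a warning.
#'
#' @param tbl a [cycle_table()].
#' @param bins a [bin_speeds()] table.
#' @return A cycle table with one row per non-empty (subject, bin), speeds
#'   replaced by bin midpoints, plus columns `speed_bin`, `speed_lo`,
#'   `speed_hi`.
#' @export
assign_and_average <- function(tbl, bins) {
  check_cycle_table(tbl)
  idx <- findInterval(tbl$speed, c(bins$lo, bins$hi[nrow(bins)]),
    rightmost.closed = FALSE
  )
  outside <- idx < 1 | idx > nrow(bins) | tbl$speed >= bins$hi[nrow(bins)]
  if (any(outside)) {
    warning(sum(outside), " cycle(s) outside the binning range dropped",
      call. = FALSE
    )
  }
  tbl <- tbl[!outside, , drop = FALSE]
  idx <- idx[!outside]
  tbl$speed_bin <- bins$bin[idx]
  out <- tbl |>
    dplyr::group_by(.data$subject, .data$speed_bin) |>
    dplyr::summarise(
      mode = .data$mode[which.max(tabulate(match(.data$mode, unique(.data$mode))))],
      values = list(Reduce(`+`, .data$values) / length(.data$values)),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      dplyr::rename(bins,
        speed_bin = "bin", speed_lo = "lo", speed_hi = "hi", speed = "mid"
      ),
      by = "speed_bin"
    ) |>
    dplyr::select(
      "subject", "speed", "speed_bin", "speed_lo", "speed_hi",
      "mode", "values"
    ) |>
    dplyr::arrange(.data$subject, .data$speed)
  n_missing <- length(unique(tbl$subject)) * nrow(bins) - nrow(out)
  if (n_missing > 0) {
    warning(n_missing, " empty (subject, bin) task(s) recorded as missing",
      call. = FALSE
    )
  }
  out
}

#' Assemble the channels x frames x tasks data tensor
#'
#' Stacks the cycle matrices of a cycle table into a [data_tensor()]. Tasks
#' are ordered subject-major with speed ascending within subject, and that
#' order is recorded in the tensor's task descriptors. Slicing task `k` of
#' the result returns the k-th cycle matrix exactly.
#'
#' @param tbl a [cycle_table()] with one row per (subject, speed).
#' @param channels optional channel labels.
#' @param nonneg flag the tensor non-negative.
#' @return A [data_tensor()] of shape `S x T x K`, `K = nrow(tbl)`.
#' @export
assemble_tensor <- function(tbl, channels = NULL, nonneg = FALSE) {
  check_cycle_table(tbl)
  tbl <- dplyr::arrange(tbl, .data$subject, .data$speed)
  if (anyDuplicated(tbl[c("subject", "speed")])) {
    stop("duplicate (subject, speed) task descriptors", call. = FALSE)
  }
  d <- dim(tbl$values[[1]])
  x <- array(0, dim = c(d[1], d[2], nrow(tbl)))
  for (k in seq_len(nrow(tbl))) x[, , k] <- tbl$values[[k]]
  if (is.null(channels)) channels <- rownames(tbl$values[[1]])
  data_tensor(x,
    channels = channels,
    tasks = dplyr::select(tbl, -"values"), nonneg = nonneg
  )
}
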