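test_that("zero-lag filter passes DC exactly and preserves symmetry", {
  x <- rep(3.7, 400)
  y <- butterworth_zero_lag(x, 15, fs = 100)
  expect_equal(y, x, tolerance = 1e-9)
  # symmetric input -> symmetric output (zero-phase property)
  t <- seq(-1, 1, length.out = 401)
  xs <- exp(-t^2 * 8) + 0.3 * cos(6 * pi * t)
  ys <- butterworth_zero_lag(xs, 10, fs = 200)
  expect_equal(ys, rev(ys), tolerance = 1e-6)
})

test_that("filter attenuation matches the squared Butterworth magnitude", {
  fs <- 1000
  fc <- 15
  n_ord <- 4
  for (f in c(5, 15, 30)) {
    t <- seq(0, 10, by = 1 / fs)
    x <- sin(2 * pi * f * t)
    y <- butterworth_zero_lag(x, fc, fs = fs, order = n_ord)
    mid <- seq(round(length(x) * 0.25), round(length(x) * 0.75))
    gain <- max(abs(y[mid])) / max(abs(x[mid]))
    analog <- (1 / sqrt(1 + (f / fc)^(2 * n_ord)))^2 # applied twice
    expect_equal(gain, analog, tolerance = 0.05)
  }
})

test_that("filter rejects invalid cutoffs and too-short signals", {
  expect_error(butterworth_zero_lag(rnorm(100), 60, fs = 100), "cutoff")
  expect_error(butterworth_zero_lag(rnorm(10), 5, fs = 100), "short")
})

test_that("rectification is symmetric and zero-preserving", {
  expect_equal(rectify_and_smooth(rep(0, 300), fs = 100), rep(0, 300))
  set.seed(1)
  x <- rnorm(500)
  e1 <- rectify_and_smooth(x, fs = 1000)
  e2 <- rectify_and_smooth(-x, fs = 1000)
  expect_identical(e1, e2)
  expect_true(all(e1 >= 0))
})

test_that("event detection equals a brute-force threshold scan", {
  brute_scan <- function(g, thr) {
    above <- g > thr
    contacts <- integer(0); toe_offs <- integer(0)
    for (i in 2:length(g)) {
      if (above[i] && !above[i - 1]) contacts <- c(contacts, i)
      if (!above[i] && above[i - 1]) toe_offs <- c(toe_offs, i)
    }
    list(contacts = contacts, toe_offs = toe_offs)
  }
  rec <- synthesize_raw_recording(12, fs = 200, cycle_duration_s = 0.9)
  ev <- detect_gait_events(rec$grf_z, fs = 200, threshold_n = 20,
                           min_phase_ms = 0)
  ref <- brute_scan(rec$grf_z, 20)
  expect_identical(ev$contacts, as.integer(ref$contacts))
  expect_identical(ev$toe_offs, as.integer(ref$toe_offs))
  # 27 stance pulses give 27 contacts and 27 toe-offs
  rec27 <- synthesize_raw_recording(27, fs = 100)
  ev27 <- detect_gait_events(rec27$grf_z, fs = 100)
  expect_length(ev27$contacts, 27)
  expect_length(ev27$toe_offs, 27)
})

test_that("event detection debounces short phases and warns on silence", {
  fs <- 1000
  g <- rep(0, 2000)
  g[500:900] <- 100
  g[700:705] <- 0 # 6 ms unloading artifact inside stance
  g[1500:1503] <- 100 # 4 ms spike
  ev <- detect_gait_events(g, fs, threshold_n = 20, min_phase_ms = 50)
  expect_identical(ev$contacts, 500L)
  expect_identical(ev$toe_offs, 901L)
  expect_warning(ev0 <- detect_gait_events(rep(0, 100), fs), "crossings")
  expect_length(ev0$contacts, 0)
})

test_that("cycle segmentation spans anchor to anchor", {
  sig <- matrix(seq_len(600), nrow = 1)
  ev <- gait_events(contacts = c(150, 350), toe_offs = c(100, 300, 500))
  cyc <- segment_cycles(sig, ev, anchor = "toe_off")
  expect_length(cyc, 2)
  expect_identical(cyc[[1]]$values[1, ], 100:299)
  expect_identical(cyc[[2]]$values[1, ], 300:499)
  expect_error(
    segment_cycles(sig, gait_events(toe_offs = 100L)),
    "at least 2"
  )
})

test_that("segmentation of a synthetic recording recovers the templates", {
  rec <- synthesize_raw_recording(8, fs = 100, cycle_duration_s = 1.1)
  cyc <- segment_cycles(rec)
  expect_length(cyc, length(rec$events$toe_offs) - 1)
  tpl <- rec$templates
  for (one in cyc) {
    z <- time_normalize(one, n_frames = ncol(tpl))
    expect_lt(max(abs(z - tpl)), 0.05)
  }
})

test_that("time normalization is exact on linear ramps and near-exact on sinusoids", {
  ramp <- rbind(seq(2, 7, length.out = 37), rep(1.5, 37))
  z <- time_normalize(ramp, n_frames = 200)
  expect_equal(z[1, ], seq(2, 7, length.out = 200), tolerance = 1e-12)
  expect_equal(z[2, ], rep(1.5, 200), tolerance = 1e-12)
  expect_equal(z[1, c(1, 200)], c(2, 7)) # endpoints preserved
  n <- 400
  s <- matrix(sin(2 * pi * seq(0, 1, length.out = n)), nrow = 1)
  z <- time_normalize(s, n_frames = 200)
  dense <- sin(2 * pi * seq(0, 1, length.out = 200))
  expect_lt(max(abs(z[1, ] - dense)), (2 * pi)^2 / (8 * (n - 1)^2) + 1e-12)
  expect_error(time_normalize(matrix(1, 2, 1)), "2 samples")
})

test_that("joint-angle standardization pools per subject and channel", {
  set.seed(21)
  mk <- function(mu, sd) matrix(rnorm(3 * 50, mu, sd), 3, 50)
  tbl <- cycle_table(
    list(mk(5, 2), mk(5, 2), mk(-1, 0.5), mk(-1, 0.5)),
    subject = c(1, 1, 2, 2), speed = c(1, 2, 1, 2),
    mode = c("walk", "run", "walk", "run")
  )
  out <- standardize_joint_angles(tbl)
  for (s in 1:2) {
    pooled <- do.call(cbind, out$values[out$subject == s])
    expect_equal(rowMeans(pooled), rep(0, 3), tolerance = 1e-12)
    expect_equal(
      apply(pooled, 1, function(v) sqrt(mean((v - mean(v))^2))),
      rep(1, 3),
      tolerance = 1e-12
    )
  }
  # naive per-(subject, channel) loop oracle on the transformation itself
  s1 <- do.call(cbind, tbl$values[tbl$subject == 1])
  ch1 <- s1[2, ]
  expected <- (tbl$values[[1]][2, ] - mean(ch1)) /
    sqrt(mean((ch1 - mean(ch1))^2))
  expect_equal(out$values[[1]][2, ], expected, tolerance = 1e-12)
  # idempotence
  out2 <- standardize_joint_angles(out)
  expect_equal(out2$values, out$values, tolerance = 1e-12)
  # zero-variance channel errors with the channel named
  tbl$values[[1]][1, ] <- 1
  tbl$values[[2]][1, ] <- 1
  rownames(tbl$values[[1]]) <- rownames(tbl$values[[2]]) <- c("hip", "knee", "ankle")
  expect_error(standardize_joint_angles(tbl), "hip")
})

test_that("EMG scaling divides by the per-subject per-muscle maximum", {
  set.seed(22)
  tbl <- cycle_table(
    list(matrix(runif(2 * 30), 2, 30), matrix(runif(2 * 30, 0, 3), 2, 30)),
    subject = c(1, 1), speed = c(1, 2), mode = c("walk", "walk")
  )
  out <- scale_emg(tbl)
  pooled <- do.call(cbind, out$values)
  expect_equal(apply(pooled, 1, max), c(1, 1), tolerance = 1e-15)
  # equals division by the naive per-channel max
  mx <- apply(do.call(cbind, tbl$values), 1, max)
  expect_equal(out$values[[2]], tbl$values[[2]] / mx, tolerance = 1e-15)
  expect_equal(scale_emg(out)$values, out$values, tolerance = 1e-15)
  tbl$values[[1]][1, ] <- -tbl$values[[1]][1, ]
  expect_error(scale_emg(tbl), "non-negative")
  tbl$values[[1]][1, ] <- 0
  tbl$values[[2]][1, ] <- 0
  expect_error(scale_emg(tbl), "all-zero")
})

test_that("speed binning reproduces the published bin and task counts", {
  expect_identical(nrow(bin_speeds(0.3, 4.3, 0.1)), 40L)
  expect_identical(nrow(bin_speeds(0.3, 5.0, 0.1)), 47L)
  b <- bin_speeds(1.0, 2.0, 0.25)
  expect_equal(b$lo, c(1.0, 1.25, 1.5, 1.75))
  expect_error(bin_speeds(2, 1), "speed_max")
})

test_that("bin assignment is half-open and averaging is the frame-wise mean", {
  bins <- bin_speeds(1.0, 2.0, 0.5)
  m1 <- matrix(1, 2, 10); m2 <- matrix(3, 2, 10); m3 <- matrix(10, 2, 10)
  tbl <- cycle_table(list(m1, m2, m3),
    subject = c(1, 1, 1), speed = c(1.2, 1.3, 1.5),
    mode = c("walk", "walk", "walk")
  )
  out <- assign_and_average(tbl, bins)
  expect_equal(nrow(out), 2)
  expect_equal(out$values[[1]], (m1 + m2) / 2) # [1.0, 1.5)
  expect_equal(out$values[[2]], m3) # 1.5 goes to the upper bin
  # a speed exactly at speed_max is excluded
  tbl2 <- cycle_table(list(m1), subject = 1, speed = 2.0, mode = "walk")
  expect_warning(out2 <- assign_and_average(tbl2, bins), "outside")
  expect_equal(nrow(out2), 0)
  # an empty bin is reported as a missing task
  tbl3 <- cycle_table(list(m1), subject = 1, speed = 1.2, mode = "walk")
  expect_warning(out3 <- assign_and_average(tbl3, bins), "missing")
  expect_equal(nrow(out3), 1)
})

test_that("tensor assembly orders tasks subject-major, speed ascending", {
  mk <- function(v) matrix(v, 2, 5)
  tbl <- cycle_table(
    list(mk(4), mk(3), mk(2), mk(1)),
    subject = c(2, 2, 1, 1), speed = c(2, 1, 2, 1),
    mode = c("run", "walk", "run", "walk")
  )
  dt <- assemble_tensor(tbl)
  expect_identical(dim(dt), c(2L, 5L, 4L))
  tasks <- task_table(dt)
  expect_equal(tasks$subject, c(1, 1, 2, 2))
  expect_equal(tasks$speed, c(1, 2, 1, 2))
  expect_equal(dt[, , 1], mk(1)) # round trip, bit-exact
  expect_equal(dt[, , 4], mk(4))
  tbl$subject <- c(1, 1, 1, 1)
  tbl$speed <- c(1, 1, 2, 2)
  expect_error(assemble_tensor(tbl), "duplicate")
})

test_that("11 speeds x 15 subjects yields 165 tasks", {
  spec <- synthetic_spec("angles")
  expect_identical(nrow(task_grid(spec)), 165L)
})
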