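test_that("component matching recovers identity and permutations exactly", {
  m <- random_cp_model(S = 6, T = 10, K = 4, R = 4, seed = 71)
  self <- match_components(m, m)
  expect_equal(self$matches$component_b, 1:4)
  expect_equal(self$matches$congruence, rep(1, 4), tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)
  mp <- m
  mp$lambda <- m$lambda[perm]
  mp$spatial <- m$spatial[, perm]
  mp$temporal <- m$temporal[, perm]
  mp$task <- m$task[, perm]
  got <- match_components(m, mp)
  expect_equal(got$matches$component_b, order(perm))
  # brute force over all permutations (independent of the implementation)
  C <- outer(1:4, 1:4, Vectorize(function(i, j) {
    congruence(
      c(m$spatial[, i], m$temporal[, i]),
      c(mp$spatial[, j], mp$temporal[, j])
    )
  }))
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  best <- max(apply(perms, 1, function(p) sum(C[cbind(1:4, as.integer(p))])))
  expect_equal(got$total, best, tolerance = 1e-12)
})

test_that("matching handles unequal ranks by matching the smaller model", {
  big <- random_cp_model(S = 5, T = 8, K = 3, R = 4, seed = 72)
  small <- big
  keep <- c(2, 4)
  small$R <- 2L
  small$lambda <- big$lambda[keep]
  small$spatial <- big$spatial[, keep]
  small$temporal <- big$temporal[, keep]
  small$task <- big$task[, keep]
  got <- match_components(small, big)
  expect_equal(got$matches$component_b, keep)
  expect_length(got$unmatched_b, 2)
})

test_that("recovery score is 1 for the model itself and after allowed sign flips", {
  m <- random_cp_model(S = 5, T = 8, K = 4, R = 3, seed = 73)
  expect_equal(recovery_score(m, m)$score, 1, tolerance = 1e-12)
  flipped <- m
  for (r in 1:3) { # flip (spatial, temporal): reconstruction-invariant
    flipped$spatial[, r] <- -flipped$spatial[, r]
    flipped$temporal[, r] <- -flipped$temporal[, r]
  }
  flipped <- normalize_components(flipped)
  canon <- normalize_components(m)
  expect_equal(recovery_score(flipped, canon)$score, 1, tolerance = 1e-12)
})

test_that("recovery of random unrelated factors is near zero on average", {
  set.seed(74)
  scores <- replicate(30, {
    a <- random_cp_model(S = 20, T = 30, K = 10, R = 1,
      seed = sample.int(1e6, 1)
    )
    b <- random_cp_model(S = 20, T = 30, K = 10, R = 1,
      seed = sample.int(1e6, 1)
    )
    recovery_score(a, b, weights_on = c("spatial", "temporal"))$score
  })
  expect_lt(abs(mean(scores)), 0.15)
})

test_that("discontinuity statistic matches direct recomputation on planted models", {
  d <- 0.6
  spec <- small_emg_spec(seed = 75, R = 3,
    profiles = c("constant", "run_specific", "speed_linear")
  )
  spec$discontinuity_size <- d
  gt <- generate_ground_truth(spec)
  ct <- mode_discontinuity(gt)
  comp <- ct$components
  # constant profile: exactly zero
  expect_equal(comp$discontinuity[gt$profiles == "constant"], 0,
    tolerance = 1e-12
  )
  # run-specific: |t_walk - t_run| from the profile formula, recomputed
  tasks <- gt$tasks
  raw <- 0.15 + d * (tasks$mode == "run")
  col <- raw / sqrt(sum(raw^2))
  kw <- ct$walk_tasks
  kr <- ct$run_tasks
  expect_equal(
    comp$discontinuity[gt$profiles == "run_specific"],
    mean(abs(col[kw] - col[kr])),
    tolerance = 1e-12
  )
  expect_equal(comp$dominance[gt$profiles == "run_specific"], "run")
  # reference tasks really are the bins containing 1.8 and 2.3 m/s
  expect_true(all(tasks$speed_lo[kw] <= 1.8 & 1.8 < tasks$speed_hi[kw]))
  expect_true(all(tasks$speed_lo[kr] <= 2.3 & 2.3 < tasks$speed_hi[kr]))
})

test_that("top-2 selection finds the planted walk- and run-specific pair", {
  spec <- small_emg_spec(seed = 76, R = 4, S = 12,
    profiles = c("speed_linear", "walk_specific", "constant", "run_specific")
  )
  gt <- generate_ground_truth(spec)
  ct <- mode_discontinuity(gt)
  sel <- ct$components[ct$components$selected, ]
  expect_setequal(
    gt$profiles[sel$component],
    c("walk_specific", "run_specific")
  )
  expect_identical(
    sel$dominance[match(c("walk_specific", "run_specific"),
                        gt$profiles[sel$component])],
    c("walk", "run")
  )
  # invariant to component reordering
  perm <- c(3, 1, 4, 2)
  gp <- gt
  gp$lambda <- gt$lambda[perm]
  gp$spatial <- gt$spatial[, perm]
  gp$temporal <- gt$temporal[, perm]
  gp$task <- gt$task[, perm]
  gp$profiles <- gt$profiles[perm]
  ctp <- mode_discontinuity(gp)
  expect_equal(
    sort(ctp$components$discontinuity),
    sort(ct$components$discontinuity),
    tolerance = 1e-12
  )
})

test_that("missing reference speeds raise a subject-named error", {
  spec <- small_emg_spec(seed = 77, R = 1, profiles = "constant")
  gt <- generate_ground_truth(spec)
  gt$tasks <- gt$tasks[gt$tasks$speed > 2.0 | gt$tasks$subject != 2, ]
  gt$task <- gt$task[seq_len(nrow(gt$tasks)), , drop = FALSE]
  expect_error(mode_discontinuity(gt), "subject 2")
})

test_that("repeated-measures ANOVA matches the hand-computed decomposition", {
  # tiny worked design: 3 subjects x 2 muscles x 2 modes
  y <- array(c(
    2.1, 1.9, 2.4, # walk, muscle 1
    3.0, 3.2, 2.7, # walk, muscle 2
    2.0, 2.2, 2.1, # run, muscle 1
    4.1, 3.9, 4.4 # run, muscle 2
  ), dim = c(3, 2, 2))
  res <- rm_anova_two_way(y)
  oracle <- manual_rm_anova(y)
  tab <- res$table
  expect_equal(tab$statistic[tab$effect == "muscle"], oracle$F_muscle,
    tolerance = 1e-10
  )
  expect_equal(tab$statistic[tab$effect == "mode"], oracle$F_mode,
    tolerance = 1e-10
  )
  expect_equal(tab$statistic[tab$effect == "muscle:mode"],
    oracle$F_interaction,
    tolerance = 1e-10
  )
  expect_equal(
    c(tab$df1[tab$effect == "muscle:mode"], tab$df2[tab$effect == "muscle:mode"]),
    oracle$df_interaction
  )
  expect_equal(res$ms_error, oracle$ms_error_interaction, tolerance = 1e-10)
})

test_that("the 16-muscle 16-subject design yields interaction df (15, 225)", {
  set.seed(78)
  y <- array(rnorm(16 * 16 * 2), dim = c(16, 16, 2))
  res <- rm_anova_two_way(y)
  int <- res$table[res$table$effect == "muscle:mode", ]
  expect_identical(c(int$df1, int$df2), c(15, 225))
  expect_true(all(res$table$p.value >= 0 & res$table$p.value <= 1))
})

test_that("ANOVA rejects incomplete designs and accepts long tables", {
  y <- expand.grid(subject = 1:4, muscle = c("a", "b"), mode = c("walk", "run"))
  y$weight <- rnorm(nrow(y))
  res <- rm_anova_two_way(y)
  expect_identical(res$n_subjects, 4L)
  expect_error(rm_anova_two_way(y[-1, ]), "balanced")
})

test_that("Tukey comparisons pick up a planted per-muscle mode effect", {
  set.seed(79)
  n <- 16; m <- 8
  y <- array(rnorm(n * m * 2, sd = 0.1), dim = c(n, m, 2))
  y[, 3, 2] <- y[, 3, 2] + 1 # muscle 3 recruited more in run mode
  res <- rm_anova_two_way(y)
  expect_true(res$interaction_significant)
  ph <- res$posthoc
  expect_lt(ph$p_adj[3], 0.01)
  expect_lt(ph$mean_walk[3] - ph$mean_run[3], 0)
  expect_gt(min(ph$p_adj[-3]), 0.05)
})

test_that("ANOVA detects a planted interaction with high power", {
  # effect size fixed by a design-phase pilot: delta = 0.45 SD of the
  # within-cell noise, concentrated on half the muscles (pilot power ~0.9)
  set.seed(80)
  n <- 16; m <- 16
  delta <- 0.45
  hits <- replicate(30, {
    y <- array(rnorm(n * m * 2), dim = c(n, m, 2))
    y[, 1:8, 1] <- y[, 1:8, 1] + delta
    y[, 1:8, 2] <- y[, 1:8, 2] - delta
    tab <- rm_anova_two_way(y)$table
    tab$p.value[tab$effect == "muscle:mode"] < 0.05
  })
  expect_gt(mean(hits), 0.8)
})
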