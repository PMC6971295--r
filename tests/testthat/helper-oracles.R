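# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the implementation it checks.

# Naive triple-loop CP reconstruction.
naive_reconstruct <- function(m) {
  S <- nrow(m$spatial); Tn <- nrow(m$temporal); K <- nrow(m$task)
  x <- array(0, dim = c(S, Tn, K))
  for (i in seq_len(S)) for (j in seq_len(Tn)) for (k in seq_len(K)) {
    x[i, j, k] <- sum(m$lambda * m$spatial[i, ] * m$temporal[j, ] * m$task[k, ])
  }
  x
}

# Scalar-loop relative fitting error.
naive_fitting_error <- function(x, xhat) {
  num <- 0; den <- 0
  for (v in seq_along(x)) {
    num <- num + (x[v] - xhat[v])^2
    den <- den + x[v]^2
  }
  num / den
}

# Reference CP solver: joint gradient-based minimization of the squared
# error over all factor entries (L-BFGS-B, multi-start). Independent of the
# ALS / multiplicative-update route.
reference_cp_objective <- function(x, R, n_starts = 10, seed = 1,
                                   maxit = 2000) {
  d <- dim(x)
  nA <- d[1] * R; nB <- d[2] * R; nC <- d[3] * R
  X1 <- matrix(x, d[1], d[2] * d[3])
  split_par <- function(par) {
    list(
      A = matrix(par[seq_len(nA)], d[1], R),
      B = matrix(par[nA + seq_len(nB)], d[2], R),
      C = matrix(par[nA + nB + seq_len(nC)], d[3], R)
    )
  }
  kr <- function(C, B) {
    out <- matrix(0, nrow(B) * nrow(C), ncol(B))
    for (r in seq_len(ncol(B))) out[, r] <- kronecker(C[, r], B[, r])
    out
  }
  fn <- function(par) {
    f <- split_par(par)
    sum((X1 - f$A %*% t(kr(f$C, f$B)))^2)
  }
  gr <- function(par) {
    f <- split_par(par)
    Z1 <- kr(f$C, f$B)
    E1 <- f$A %*% t(Z1) - X1 # residual, mode-1 unfolding
    gA <- 2 * E1 %*% Z1
    E <- array(E1, d)
    X2 <- matrix(aperm(E, c(2, 1, 3)), d[2], d[1] * d[3])
    gB <- 2 * X2 %*% kr(f$C, f$A)
    X3 <- matrix(aperm(E, c(3, 1, 2)), d[3], d[1] * d[2])
    gC <- 2 * X3 %*% kr(f$B, f$A)
    c(gA, gB, gC)
  }
  best <- Inf
  for (i in seq_len(n_starts)) {
    set.seed(seed + i)
    p0 <- stats::rnorm(nA + nB + nC, sd = 0.7)
    o <- stats::optim(p0, fn, gr,
      method = "L-BFGS-B",
      control = list(maxit = maxit, factr = 10)
    )
    best <- min(best, o$value)
  }
  best
}

# Hand-computed balanced within-subject two-way ANOVA (flat mean algebra).
manual_rm_anova <- function(y) { # y: subjects x muscles x modes
  ns <- dim(y)[1]; na <- dim(y)[2]; nb <- dim(y)[3]
  m <- mean(y)
  ms <- apply(y, 1, mean); ma <- apply(y, 2, mean); mb <- apply(y, 3, mean)
  msa <- apply(y, c(1, 2), mean); msb <- apply(y, c(1, 3), mean)
  mab <- apply(y, c(2, 3), mean)
  ss_a <- ns * nb * sum((ma - m)^2)
  ss_as <- nb * sum((msa - outer(ms, rep(1, na)) -
                       outer(rep(1, ns), ma) + m)^2)
  ss_b <- ns * na * sum((mb - m)^2)
  ss_bs <- na * sum((msb - outer(ms, rep(1, nb)) -
                       outer(rep(1, ns), mb) + m)^2)
  ss_ab <- ns * sum((mab - outer(ma, rep(1, nb)) -
                       outer(rep(1, na), mb) + m)^2)
  resid <- y
  for (s in seq_len(ns)) for (a in seq_len(na)) for (b in seq_len(nb)) {
    resid[s, a, b] <- y[s, a, b] - msa[s, a] - msb[s, b] - mab[a, b] +
      ms[s] + ma[a] + mb[b] - m
  }
  ss_abs <- sum(resid^2)
  f_a <- (ss_a / (na - 1)) / (ss_as / ((na - 1) * (ns - 1)))
  f_b <- (ss_b / (nb - 1)) / (ss_bs / ((nb - 1) * (ns - 1)))
  df_ab <- (na - 1) * (nb - 1)
  df_abs <- df_ab * (ns - 1)
  f_ab <- (ss_ab / df_ab) / (ss_abs / df_abs)
  list(
    F_muscle = f_a, F_mode = f_b, F_interaction = f_ab,
    df_interaction = c(df_ab, df_abs),
    ms_error_interaction = ss_abs / df_abs
  )
}

# Small planted fixtures shared by several files.
small_emg_spec <- function(seed = 1, R = 3, noise_sd = 0, S = 8, T = 40,
                           n_subjects = 3,
                           profiles = c("speed_linear", "walk_specific",
                                        "run_specific")[seq_len(R)]) {
  synthetic_spec("emg",
    S = S, T = T, R = R, n_subjects = n_subjects,
    speed_min = 0.5, speed_max = 2.5, noise_sd = noise_sd,
    profiles = profiles, seed = seed
  )
}

small_angle_spec <- function(seed = 1, R = 3, noise_sd = 0, S = 6, T = 40,
                             n_subjects = 4) {
  synthetic_spec("angles",
    S = S, T = T, R = R, n_subjects = n_subjects,
    noise_sd = noise_sd, seed = seed
  )
}

random_cp_model <- function(S = 4, T = 5, K = 3, R = 2, nonneg = FALSE,
                            seed = 1) {
  set.seed(seed)
  draw <- function(n) {
    m <- matrix(if (nonneg) stats::runif(n * R) else stats::rnorm(n * R), n, R)
    m
  }
  cp_model(stats::runif(R, 0.5, 2), draw(S), draw(T), draw(K),
    nonneg = nonneg
  )
}
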