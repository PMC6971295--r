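#' CP (CANDECOMP/PARAFAC) model of a locomotion tensor
#'
#' A rank-`R` CP model approximates the data tensor as a sum of `R` rank-1
#' terms, `X[i,j,k] ~ sum_r lambda_r * w[i,r] * p[j,r] * t[k,r]`, where each
#' component couples a spatial module `w_r` (a weighting over channels), a
#' temporal module `p_r` (an activation profile over the gait cycle) and a
#' task-dependent modulation `t_r` (a recruitment gain per task). Factor
#' columns are unit Euclidean norm; all scale lives in the non-negative
#' weights `lambda`, stored in descending order.
#'
#' @param lambda numeric vector of `R` non-negative component weights.
#' @param spatial `S x R` spatial factor matrix.
#' @param temporal `T x R` temporal factor matrix.
#' @param task `K x R` task factor matrix.
#' @param nonneg logical; `TRUE` for a non-negativity-constrained model.
#' @param normalize if `TRUE` (default) pass the factors through
#'   [normalize_components()] so the invariants hold.
#' @param channels,tasks optional labels carried over from the tensor.
#' @return An object of class `cp_model`.
#' @export
cp_model <- function(lambda, spatial, temporal, task, nonneg = FALSE,
                     normalize = TRUE, channels = NULL, tasks = NULL) {
  spatial <- as.matrix(spatial)
  temporal <- as.matrix(temporal)
  task <- as.matrix(task)
  R <- length(lambda)
  if (ncol(spatial) != R || ncol(temporal) != R || ncol(task) != R) {
    stop("factor matrices must all have ", R, " columns", call. = FALSE)
  }
  if (any(lambda < 0)) stop("lambda must be non-negative", call. = FALSE)
  m <- structure(
    list(
      R = R, lambda = as.numeric(lambda),
      spatial = spatial, temporal = temporal, task = task,
      nonneg = isTRUE(nonneg),
      sign_flips = integer(0),
      channels = channels, tasks = tasks
    ),
    class = "cp_model"
  )
  if (normalize) normalize_components(m) else m
}

#' @export
print.cp_model <- function(x, ...) {
  cat(sprintf(
    "<cp_model> R = %d, %d channels x %d frames x %d tasks%s\n",
    x$R, nrow(x$spatial), nrow(x$temporal), nrow(x$task),
    if (x$nonneg) ", non-negative" else ""
  ))
  cat("lambda:", format(signif(x$lambda, 4)), "\n")
  invisible(x)
}

#' Normalize, sign-fix and order the components of a CP model
#'
#' Rescales every factor column to unit Euclidean norm, absorbing the norms
#' into the component weights `lambda`; sorts components by `lambda`
#' descending (degenerate all-zero components keep `lambda = 0` and sink to
#' the end); and, for unconstrained models, resolves the two-factor sign
#' indeterminacy of CP (flipping the signs of any two factors of a component
#' leaves the reconstruction unchanged) by flipping the (spatial, temporal)
#' pair whenever the largest-magnitude element of the temporal column is
#' negative. The reconstruction is invariant under all of this.
#'
#' @param m a `cp_model` (possibly with non-normalized factors).
#' @return The normalized `cp_model`; indices of sign-flipped components are
#'   recorded in `$sign_flips`.
#' @export
normalize_components <- function(m) {
  stopifnot(inherits(m, "cp_model"))
  R <- m$R
  lambda <- if (length(m$lambda)) m$lambda else rep(1, R)
  flips <- integer(0)
  for (r in seq_len(R)) {
    for (f in c("spatial", "temporal", "task")) {
      nrm <- sqrt(sum(m[[f]][, r]^2))
      if (nrm > 0) {
        m[[f]][, r] <- m[[f]][, r] / nrm
        lambda[r] <- lambda[r] * nrm
      }
    }
    if (lambda[r] < 0) { # fold a negative weight into two factor signs
      lambda[r] <- -lambda[r]
      m$spatial[, r] <- -m$spatial[, r]
      m$temporal[, r] <- -m$temporal[, r]
    }
    if (sum(m$spatial[, r]^2) == 0 || sum(m$temporal[, r]^2) == 0 ||
        sum(m$task[, r]^2) == 0) {
      lambda[r] <- 0
    }
    if (!m$nonneg) {
      peak <- which.max(abs(m$temporal[, r]))
      if (length(peak) && m$temporal[peak, r] < 0) {
        m$temporal[, r] <- -m$temporal[, r]
        m$spatial[, r] <- -m$spatial[, r]
        flips <- c(flips, r)
      }
      # the (spatial, task) pair can still flip jointly without changing the
      # reconstruction or the temporal sign; canonicalize it the same way
      peak <- which.max(abs(m$spatial[, r]))
      if (length(peak) && m$spatial[peak, r] < 0) {
        m$spatial[, r] <- -m$spatial[, r]
        m$task[, r] <- -m$task[, r]
        flips <- unique(c(flips, r))
      }
    }
  }
  ord <- order(lambda, decreasing = TRUE)
  m$lambda <- lambda[ord]
  m$spatial <- m$spatial[, ord, drop = FALSE]
  m$temporal <- m$temporal[, ord, drop = FALSE]
  m$task <- m$task[, ord, drop = FALSE]
  m$sign_flips <- sort(match(flips, ord))
  m$component_order <- ord
  m
}

#' Reconstruct the tensor approximated by a CP model
#'
#' Evaluates `Xhat[i,j,k] = sum_r lambda_r w[i,r] p[j,r] t[k,r]`; slice `k`
#' equals the lambda-weighted sum of rank-1 matrices `w_r p_r'` scaled by
#' `t[k,r]`.
#'
#' @param m a `cp_model`.
#' @return A [data_tensor()] of shape `S x T x K`.
#' @export
reconstruct <- function(m) {
  stopifnot(inherits(m, "cp_model"))
  ws <- sweep(m$spatial, 2, m$lambda, `*`)
  x1 <- ws %*% t(khatri_rao(m$task, m$temporal))
  x <- array(x1, dim = c(nrow(m$spatial), nrow(m$temporal), nrow(m$task)))
  data_tensor(x, channels = m$channels, tasks = m$tasks, nonneg = FALSE)
}

#' Fitting error and variance accounted for
#'
#' `fitting_error()` is the relative squared reconstruction error
#' `sum((X - Xhat)^2) / sum(X^2)`; `variance_explained()` is its complement,
#' the uncentered coefficient of determination `1 - fitting_error`. The two
#' always sum to exactly 1. For an all-zero tensor the convention is
#' `variance_explained = 1` when the reconstruction is also zero, and an
#' error otherwise.
#'
#' @param dt a [data_tensor()] (or 3-d array).
#' @param m a `cp_model` with matching dimensions.
#' @return A scalar.
#' @export
fitting_error <- function(dt, m) {
  xhat <- as_plain_array(reconstruct(m))
  x <- as_plain_array(dt)
  if (!identical(dim(x), dim(xhat))) {
    stop("tensor and model dimensions do not match", call. = FALSE)
  }
  den <- sum(x^2)
  if (den == 0) {
    if (sum(xhat^2) == 0) return(0)
    stop("fitting error undefined: zero tensor, non-zero model", call. = FALSE)
  }
  sum((x - xhat)^2) / den
}

#' @rdname fitting_error
#' @export
variance_explained <- function(dt, m) 1 - fitting_error(dt, m)

# Squared-error objective from precomputed unfoldings, with the scale carried
# in `scaled` (mode-3 MTTKRP result reused from the sweep when available).
cp_objective <- function(normX2, m3, A1, A2, A3) {
  g <- crossprod(A1) * crossprod(A2) * crossprod(A3)
  ip <- sum(m3 * A3)
  max(normX2 - 2 * ip + sum(g), 0)
}

solve_gram <- function(V, Mt) {
  out <- tryCatch(solve(V, Mt), error = function(e) NULL)
  if (is.null(out)) {
    warning("rank-deficient ALS system; using ridge-regularized solve",
      call. = FALSE
    )
    out <- solve(V + diag(1e-10 * (mean(diag(V)) + 1), nrow(V)), Mt)
  }
  out
}

cp_zero_fit <- function(dt, R, nonneg) {
  d <- dim(dt)
  m <- cp_model(rep(0, R), matrix(0, d[1], R), matrix(0, d[2], R),
    matrix(0, d[3], R),
    nonneg = nonneg, normalize = FALSE,
    channels = channel_labels(dt), tasks = task_table(dt)
  )
  m$diagnostics <- list(
    objective = 0, rel_fitting_error = 0, vaf = 1, n_iter = 0L,
    converged = TRUE, n_restarts = 0L, best_restart_seed = NA_integer_,
    trace = numeric(0)
  )
  class(m) <- c("cp_fit", "cp_model")
  m
}

cp_fit_engine <- function(dt, R, nonneg, max_iter, tol, n_restarts, seed) {
  x <- as_plain_array(dt)
  d <- dim(x)
  X1 <- unfold_tensor(x, 1L)
  X2 <- unfold_tensor(x, 2L)
  X3 <- unfold_tensor(x, 3L)
  normX2 <- sum(x^2)
  eps <- 1e-12

  run_one <- function(rseed) {
    set.seed(rseed)
    A1 <- if (nonneg) matrix(stats::runif(d[1] * R), d[1], R) else
      matrix(stats::rnorm(d[1] * R), d[1], R)
    A2 <- if (nonneg) matrix(stats::runif(d[2] * R), d[2], R) else
      matrix(stats::rnorm(d[2] * R), d[2], R)
    A3 <- if (nonneg) matrix(stats::runif(d[3] * R), d[3], R) else
      matrix(stats::rnorm(d[3] * R), d[3], R)
    trace <- numeric(0)
    obj_prev <- Inf
    converged <- FALSE
    it <- 0L
    m3 <- NULL
    while (it < max_iter) {
      it <- it + 1L
      if (nonneg) {
        Z <- khatri_rao(A3, A2)
        num <- X1 %*% Z
        A1 <- A1 * num / pmax(A1 %*% (crossprod(A2) * crossprod(A3)), eps)
        Z <- khatri_rao(A3, A1)
        num <- X2 %*% Z
        A2 <- A2 * num / pmax(A2 %*% (crossprod(A1) * crossprod(A3)), eps)
        Z <- khatri_rao(A2, A1)
        m3 <- X3 %*% Z
        A3 <- A3 * m3 / pmax(A3 %*% (crossprod(A1) * crossprod(A2)), eps)
        # m3 depends only on A1, A2, so it stays valid for the objective
      } else {
        V <- crossprod(A2) * crossprod(A3)
        A1 <- t(solve_gram(V, t(X1 %*% khatri_rao(A3, A2))))
        n1 <- pmax(sqrt(colSums(A1^2)), eps)
        A1 <- sweep(A1, 2, n1, `/`)
        V <- crossprod(A1) * crossprod(A3)
        A2 <- t(solve_gram(V, t(X2 %*% khatri_rao(A3, A1))))
        n2 <- pmax(sqrt(colSums(A2^2)), eps)
        A2 <- sweep(A2, 2, n2, `/`)
        V <- crossprod(A1) * crossprod(A2)
        m3 <- X3 %*% khatri_rao(A2, A1)
        A3 <- t(solve_gram(V, t(m3)))
      }
      obj <- cp_objective(normX2, m3, A1, A2, A3)
      trace <- c(trace, obj)
      if (is.finite(obj_prev) &&
          abs(obj_prev - obj) <= tol * max(obj_prev, eps)) {
        converged <- TRUE
        break
      }
      obj_prev <- obj
    }
    list(
      A1 = A1, A2 = A2, A3 = A3, objective = trace[length(trace)],
      trace = trace, n_iter = it, converged = converged, seed = rseed
    )
  }

  runs <- lapply(seq_len(n_restarts) - 1L, function(i) run_one(seed + i))
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "objective"))]]

  m <- cp_model(rep(1, R), best$A1, best$A2, best$A3,
    nonneg = nonneg, normalize = TRUE,
    channels = channel_labels(dt), tasks = task_table(dt)
  )
  fe <- best$objective / normX2
  m$diagnostics <- list(
    objective = best$objective,
    rel_fitting_error = fe,
    vaf = 1 - fe,
    n_iter = best$n_iter,
    converged = best$converged,
    n_restarts = n_restarts,
    best_restart_seed = best$seed,
    trace = best$trace
  )
  class(m) <- c("cp_fit", "cp_model")
  m
}

#' Fit a CP decomposition by alternating least squares
#'
#' Unconstrained CP fit minimizing the squared reconstruction error. Each
#' sweep solves the exact least-squares update for one factor matrix at a
#' time via the matricized-tensor-times-Khatri-Rao-product system, so the
#' objective is non-increasing sweep to sweep. Multiple random restarts are
#' run and the fit with the lowest final objective is kept; the returned
#' model is normalized, sign-fixed and ordered by [normalize_components()].
#'
#' @param dt a [data_tensor()] (finite values; any sign).
#' @param R rank, the number of components (>= 1).
#' @param max_iter maximum ALS sweeps per restart.
#' @param tol stop when the relative objective decrease falls below `tol`.
#' @param n_restarts number of random restarts.
#' @param seed integer seed; restart `i` uses `seed + i - 1`.
#' @return A `cp_fit` (a [cp_model()] with a `diagnostics` list: final
#'   objective, relative fitting error, variance accounted for, iteration
#'   count, convergence flag, restart bookkeeping, objective trace).
#' @export
#' @examples
#' dt <- synthesize_tensor(generate_ground_truth(
#'   synthetic_spec(S = 5, T = 30, R = 2, n_subjects = 2, nonneg = FALSE)
#' ), noise_sd = 0, seed = 1)
#' fit <- cp_als(dt, R = 2, n_restarts = 2, seed = 1)
#' glance(fit)
cp_als <- function(dt, R, max_iter = 500L, tol = 1e-8, n_restarts = 10L,
                   seed = 1L) {
  stopifnot(R >= 1)
  if (anyNA(dt)) stop("tensor contains NA", call. = FALSE)
  if (sum(as_plain_array(dt)^2) == 0) return(cp_zero_fit(dt, R, FALSE))
  cp_fit_engine(dt, R,
    nonneg = FALSE, max_iter = max_iter, tol = tol,
    n_restarts = n_restarts, seed = seed
  )
}

#' Fit a non-negative CP decomposition by multiplicative updates
#'
#' Non-negativity-constrained CP fit for EMG-like data (all factor entries
#' `>= 0`), using NMF-style multiplicative updates applied mode-wise. Each
#' factor update keeps the squared-error objective non-increasing and
#' preserves non-negativity; denominators are floored at `1e-12`.
#'
#' @inheritParams cp_als
#' @return A `cp_fit`, as for [cp_als()], with all factor entries >= 0.
#' @export
cp_nonneg <- function(dt, R, max_iter = 500L, tol = 1e-8, n_restarts = 10L,
                      seed = 1L) {
  stopifnot(R >= 1)
  if (any(as_plain_array(dt) < 0)) {
    stop("cp_nonneg requires a non-negative tensor", call. = FALSE)
  }
  if (sum(as_plain_array(dt)^2) == 0) return(cp_zero_fit(dt, R, TRUE))
  cp_fit_engine(dt, R,
    nonneg = TRUE, max_iter = max_iter, tol = tol,
    n_restarts = n_restarts, seed = seed
  )
}

#' Select the number of components by variance accounted for
#'
#' Fits CP models of rank `1..R_max` and returns the smallest rank whose
#' variance accounted for strictly exceeds `threshold` (the "more than 70%"
#' rule; 0.8 is used for per-subject analyses), together with the full
#' VAF / fitting-error curve.
#'
#' @param dt a [data_tensor()].
#' @param threshold VAF threshold in (0, 1); strict inequality is required.
#' @param R_max largest rank to try.
#' @param solver `"als"` (unconstrained) or `"nonneg"`.
#' @param ... passed to the solver ([cp_als()] / [cp_nonneg()]).
#' @param keep_fit return the fit at the selected rank as `$fit`.
#' @return A list with `R` (selected rank), `curve` (tibble with columns
#'   `R`, `vaf`, `fitting_error`) and optionally `fit`. If no rank up to
#'   `R_max` exceeds the threshold an error reports the best VAF reached.
#' @export
select_rank <- function(dt, threshold = 0.7, R_max = 10L,
                        solver = c("als", "nonneg"), ..., keep_fit = TRUE) {
  stopifnot(threshold > 0, threshold < 1, R_max >= 1)
  solver <- match.arg(solver)
  fit_fun <- if (solver == "als") cp_als else cp_nonneg
  vafs <- numeric(0)
  sel <- NULL
  for (R in seq_len(R_max)) {
    f <- fit_fun(dt, R, ...)
    vafs[R] <- f$diagnostics$vaf
    if (is.null(sel) && vafs[R] > threshold) {
      sel <- list(R = R, fit = f)
      break
    }
  }
  curve <- tibble::tibble(
    R = seq_along(vafs), vaf = vafs, fitting_error = 1 - vafs
  )
  if (is.null(sel)) {
    stop(sprintf(
      "no rank up to %d exceeds VAF threshold %.3g (best VAF %.4f)",
      R_max, threshold, max(vafs)
    ), call. = FALSE)
  }
  out <- list(R = sel$R, curve = curve, threshold = threshold)
  if (keep_fit) out$fit <- sel$fit
  out
}

#' Fitting-parameter counts: CP versus matrix decompositions
#'
#' Number of fitted parameters per configuration for rank `R`: CP
#' decomposition estimates `(S + T + K) * R` parameters; matrix decomposition
#' of the stacked `S x (T*K)` matrix estimates `(S + T*K) * R`; decomposing
#' each task's `S x T` matrix separately estimates `S * T * K * R`.
#'
#' @param S,T,K channel, frame and task counts.
#' @param R rank.
#' @return A tibble with columns `method` and `parameters`.
#' @export
#' @examples
#' parameter_counts(16, 200, 696, 1)
parameter_counts <- function(S, T, K, R = 1) {
  stopifnot(S >= 1, T >= 1, K >= 1, R >= 1)
  tibble::tibble(
    method = c("cp", "stacked_matrix", "separate_matrix"),
    parameters = c(
      (S + T + K) * R,
      (S + T * K) * R,
      S * T * K * R
    )
  )
}
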