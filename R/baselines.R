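#' PCA baseline on the stacked channel-by-(time x task) matrix
#'
#' The matrix-decomposition comparison: the tensor is stacked as
#' `Z (S x T*K)` and approximated as `Z ~ sum_r w_r p_r'`, with spatial
#' modules `w_r` constrained to be mutually orthogonal. By default the SVD
#' is uncentered so the variance-accounted-for convention matches the
#' tensor fits (centered PCA is available behind `center`). The temporal
#' modules absorb the singular values, and their per-task curves are
#' obtained with [unstack_temporal()].
#'
#' @param z an `S x (T*K)` matrix (from [stack_tasks()]) or a
#'   [data_tensor()], which is stacked first.
#' @param R number of modules; at most `min(S, T*K)`.
#' @param center subtract row means before the SVD.
#' @return A list of class `matrix_model`: `spatial` (`S x R`,
#'   orthonormal), `temporal_stacked` (`(T*K) x R`), `method`, `vaf`,
#'   `vaf_curve` (tibble), `n_frames`/`n_tasks` when known.
#' @export
pca_modules <- function(z, R, center = FALSE) {
  meta <- stack_meta(z)
  z <- meta$z
  if (R > min(dim(z))) {
    stop("R may not exceed min(S, T*K) = ", min(dim(z)), call. = FALSE)
  }
  mu <- if (center) rowMeans(z) else numeric(nrow(z))
  sv <- svd(z - mu)
  spatial <- sv$u[, seq_len(R), drop = FALSE]
  temporal <- sv$v[, seq_len(R), drop = FALSE] %*%
    diag(sv$d[seq_len(R)], R, R)
  den <- sum(z^2)
  resid <- rev(cumsum(rev(sv$d^2))) # Eckart-Young tail energies
  vaf_curve <- 1 - (c(resid[-1], 0) + if (center) 0 else 0) / den
  if (center) { # reconstruction includes the row means
    vaf_curve <- vapply(seq_along(sv$d), function(r) {
      zr <- sv$u[, seq_len(r), drop = FALSE] %*%
        diag(sv$d[seq_len(r)], r, r) %*%
        t(sv$v[, seq_len(r), drop = FALSE]) + mu
      1 - sum((z - zr)^2) / den
    }, numeric(1))
  }
  structure(
    list(
      spatial = spatial, temporal_stacked = temporal, method = "pca",
      center = center, row_means = mu,
      vaf = vaf_curve[R],
      vaf_curve = tibble::tibble(R = seq_along(vaf_curve), vaf = vaf_curve),
      singular_values = sv$d,
      n_frames = meta$n_frames, n_tasks = meta$n_tasks
    ),
    class = "matrix_model"
  )
}

#' NNMF baseline on the stacked matrix
#'
#' Non-negative matrix factorization `Z ~ W H` of the stacked
#' `S x (T*K)` matrix by multiplicative updates (squared-error objective,
#' non-increasing each sweep), best of several random restarts. Spatial module
#' columns are rescaled to unit norm with the scale absorbed into the
#' temporal modules. No orthogonality is imposed; all entries stay
#' non-negative.
#'
#' @inheritParams pca_modules
#' @param max_iter,tol,n_restarts,seed solver options as in [cp_nonneg()].
#' @return A `matrix_model` (as for [pca_modules()]) with `method = "nnmf"`
#'   and an `objective_trace`.
#' @export
nnmf_modules <- function(z, R, max_iter = 500L, tol = 1e-8,
                         n_restarts = 10L, seed = 1L) {
  meta <- stack_meta(z)
  z <- meta$z
  if (any(z < 0)) stop("NNMF requires a non-negative matrix", call. = FALSE)
  S <- nrow(z)
  TK <- ncol(z)
  den <- sum(z^2)
  eps <- 1e-12
  run_one <- function(rseed) {
    set.seed(rseed)
    W <- matrix(stats::runif(S * R), S, R)
    H <- matrix(stats::runif(R * TK), R, TK)
    trace <- numeric(0)
    obj_prev <- Inf
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      W <- W * (z %*% t(H)) / pmax(W %*% (H %*% t(H)), eps)
      H <- H * (t(W) %*% z) / pmax(crossprod(W) %*% H, eps)
      obj <- den - 2 * sum((t(W) %*% z) * H) + sum(crossprod(W) * (H %*% t(H)))
      obj <- max(obj, 0)
      trace <- c(trace, obj)
      if (is.finite(obj_prev) &&
          abs(obj_prev - obj) <= tol * max(obj_prev, eps)) {
        converged <- TRUE
        break
      }
      obj_prev <- obj
    }
    list(W = W, H = H, objective = trace[length(trace)], trace = trace,
         converged = converged)
  }
  runs <- lapply(seq_len(n_restarts) - 1L, function(i) run_one(seed + i))
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "objective"))]]
  nrm <- pmax(sqrt(colSums(best$W^2)), eps)
  W <- sweep(best$W, 2, nrm, `/`)
  H <- best$H * nrm
  structure(
    list(
      spatial = W, temporal_stacked = t(H), method = "nnmf",
      vaf = 1 - best$objective / den,
      vaf_curve = tibble::tibble(R = R, vaf = 1 - best$objective / den),
      objective = best$objective, objective_trace = best$trace,
      converged = best$converged,
      n_frames = meta$n_frames, n_tasks = meta$n_tasks
    ),
    class = "matrix_model"
  )
}

stack_meta <- function(z) {
  if (inherits(z, "data_tensor")) {
    d <- dim(z)
    list(z = stack_tasks(z), n_frames = d[2], n_tasks = d[3])
  } else {
    list(
      z = as.matrix(z),
      n_frames = attr(z, "n_frames"), n_tasks = attr(z, "n_tasks")
    )
  }
}

#' Reconstruct the stacked matrix approximated by a matrix model
#'
#' @param m a `matrix_model`.
#' @return The `S x (T*K)` reconstruction `W H (+ row means if centered)`.
#' @export
reconstruct_matrix <- function(m) {
  stopifnot(inherits(m, "matrix_model"))
  out <- m$spatial %*% t(m$temporal_stacked)
  if (isTRUE(m$center)) out <- out + m$row_means
  out
}

#' @export
print.matrix_model <- function(x, ...) {
  cat(sprintf(
    "<matrix_model> %s, R = %d, VAF = %.4f\n",
    x$method, ncol(x$spatial), x$vaf
  ))
  invisible(x)
}
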