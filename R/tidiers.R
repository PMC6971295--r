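#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a CP model into a long factor table
#'
#' One row per (component, factor, index): spatial rows carry the channel
#' label, temporal rows the frame, task rows the task descriptors (subject,
#' speed, mode) when available.
#'
#' @param x a `cp_model` or `cp_fit`.
#' @param ... unused.
#' @return A tibble with columns `component`, `lambda`, `part`, `index`,
#'   `label`, `value` and any task descriptor columns.
#' @method tidy cp_model
#' @export
tidy.cp_model <- function(x, ...) {
  part_tbl <- function(part, mat, labels = NULL) {
    tibble::tibble(
      component = rep(seq_len(x$R), each = nrow(mat)),
      lambda = rep(x$lambda, each = nrow(mat)),
      part = part,
      index = rep(seq_len(nrow(mat)), times = x$R),
      label = if (is.null(labels)) {
        as.character(rep(seq_len(nrow(mat)), times = x$R))
      } else {
        rep(as.character(labels), times = x$R)
      },
      value = as.numeric(mat)
    )
  }
  out <- dplyr::bind_rows(
    part_tbl("spatial", x$spatial, x$channels),
    part_tbl("temporal", x$temporal),
    part_tbl("task", x$task)
  )
  if (!is.null(x$tasks)) {
    keep <- intersect(c("subject", "speed", "mode"), names(x$tasks))
    desc <- x$tasks[keep]
    desc$part <- "task"
    desc$index <- seq_len(nrow(desc))
    out <- dplyr::left_join(out, desc, by = c("part", "index"))
  }
  out
}

#' Fit summary of a CP fit
#'
#' @param x a `cp_fit`.
#' @param ... unused.
#' @return A one-row tibble: rank, variance accounted for, fitting error,
#'   final objective, iterations, convergence, restarts.
#' @method glance cp_fit
#' @export
glance.cp_fit <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    R = x$R, vaf = d$vaf, fitting_error = d$rel_fitting_error,
    objective = d$objective, n_iter = d$n_iter, converged = d$converged,
    n_restarts = d$n_restarts
  )
}

#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) x$table

#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  int <- x$table[x$table$effect == "muscle:mode", ]
  tibble::tibble(
    statistic = int$statistic, df1 = int$df1, df2 = int$df2,
    p.value = int$p.value,
    interaction_significant = x$interaction_significant,
    n_subjects = x$n_subjects, n_muscles = x$n_muscles
  )
}

#' @method tidy mode_contrast
#' @export
tidy.mode_contrast <- function(x, ...) x$components

#' @method tidy component_match
#' @export
tidy.component_match <- function(x, ...) x$matches

#' @method tidy matrix_model
#' @export
tidy.matrix_model <- function(x, ...) {
  R <- ncol(x$spatial)
  dplyr::bind_rows(
    tibble::tibble(
      component = rep(seq_len(R), each = nrow(x$spatial)),
      part = "spatial",
      index = rep(seq_len(nrow(x$spatial)), times = R),
      value = as.numeric(x$spatial)
    ),
    tibble::tibble(
      component = rep(seq_len(R), each = nrow(x$temporal_stacked)),
      part = "temporal_stacked",
      index = rep(seq_len(nrow(x$temporal_stacked)), times = R),
      value = as.numeric(x$temporal_stacked)
    )
  )
}

#' @method glance matrix_model
#' @export
glance.matrix_model <- function(x, ...) {
  tibble::tibble(
    method = x$method, R = ncol(x$spatial), vaf = x$vaf
  )
}
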