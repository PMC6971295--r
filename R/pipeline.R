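#' Pipeline configuration
#'
#' A single declarative document holding every tunable of the pipeline:
#' the synthetic-study design, solver options, the rank-selection
#' threshold, reference speeds for the walk-run contrast and the
#' per-subject analysis switch. The resolved configuration is echoed into
#' every artifact [run_pipeline()] writes, and can be round-tripped through
#' YAML or JSON.
#'
#' @param seed master seed for the whole run.
#' @param spec named list of overrides passed to [synthetic_spec()].
#' @param threshold VAF threshold for rank selection.
#' @param R_max largest rank tried.
#' @param solver `"auto"` (non-negative tensors use multiplicative
#'   updates, signed tensors ALS), `"als"` or `"nonneg"`.
#' @param max_iter,tol,n_restarts solver options.
#' @param walk_ref,run_ref reference speeds (m/s) for the discontinuity
#'   statistic.
#' @param per_subject also fit each subject separately (at the selected
#'   rank) and run the muscle-by-mode ANOVA on the walk- and run-dominant
#'   spatial modules.
#' @param alpha significance level for the ANOVA gate.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, spec = list(), threshold = 0.7,
                            R_max = 10L, solver = "auto",
                            max_iter = 200L, tol = 1e-6, n_restarts = 3L,
                            walk_ref = 1.8, run_ref = 2.3,
                            per_subject = FALSE, alpha = 0.05) {
  structure(list(
    seed = as.integer(seed), spec = spec, threshold = threshold,
    R_max = as.integer(R_max), solver = solver,
    max_iter = as.integer(max_iter), tol = tol,
    n_restarts = as.integer(n_restarts),
    walk_ref = walk_ref, run_ref = run_ref,
    per_subject = isTRUE(per_subject), alpha = alpha
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path file to read or write (`.yaml`/`.yml` or `.json`).
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(unclass(config), path)
  } else {
    jsonlite::write_json(unclass(config), path,
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the pipeline end to end under one configuration and seed:
#' simulate (planted ground truth and noisy tensor), decompose (rank
#' selection by variance accounted for, CP fit at the selected rank),
#' analyze (walk-run discontinuity contrast, recovery of the planted
#' components and, optionally, per-subject fits feeding the muscle-by-mode
#' repeated-measures ANOVA). Identical configurations give identical
#' outputs. If `out_dir` is given, the tensor, model, diagnostics and a
#' resolved-config snapshot are written there as plain-text artifacts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return A list of class `pipeline_result`: `truth`, `tensor`,
#'   `selection` (from [select_rank()]), `fit`, `contrast`, `recovery`,
#'   optionally `anova` and `per_subject`, plus the resolved `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        call. = FALSE
      )
    })
  }
  spec <- stage("simulate", do.call(
    synthetic_spec, utils::modifyList(list(seed = config$seed), config$spec)
  ))
  truth <- stage("simulate", generate_ground_truth(spec))
  tensor <- stage("simulate", synthesize_tensor(truth))
  solver <- if (config$solver == "auto") {
    if (spec$nonneg) "nonneg" else "als"
  } else {
    config$solver
  }
  selection <- stage("decompose", select_rank(
    tensor,
    threshold = config$threshold, R_max = config$R_max, solver = solver,
    max_iter = config$max_iter, tol = config$tol,
    n_restarts = config$n_restarts, seed = config$seed + 10L
  ))
  fit <- selection$fit
  contrast <- stage("analyze", mode_discontinuity(
    fit,
    walk_ref = config$walk_ref, run_ref = config$run_ref
  ))
  recovery <- stage("analyze", recovery_score(fit, truth))
  out <- list(
    truth = truth, tensor = tensor, selection = selection, fit = fit,
    contrast = contrast, recovery = recovery, config = config
  )
  if (config$per_subject) {
    out <- c(out, stage("analyze", per_subject_analysis(
      tensor, selection$R, solver, config
    )))
  }
  class(out) <- "pipeline_result"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stage("write", {
      write_data_tensor(tensor, file.path(out_dir, "tensor"),
        extra = list(seed = config$seed)
      )
      write_cp_model(fit, file.path(out_dir, "model.json"),
        extra = list(seed = config$seed)
      )
      jsonlite::write_json(
        fit$diagnostics[c(
          "objective", "rel_fitting_error", "vaf", "n_iter", "converged",
          "n_restarts", "best_restart_seed"
        )],
        file.path(out_dir, "diagnostics.json"),
        auto_unbox = TRUE, digits = NA
      )
      write_pipeline_config(config, file.path(out_dir, "config.yaml"))
    })
  }
  out
}

# Fit each subject's slab at rank R, pick its walk- and run-dominant
# components, and assemble the subject x muscle x mode spatial-weight array
# for the repeated-measures ANOVA.
per_subject_analysis <- function(tensor, R, solver, config) {
  tasks <- task_table(tensor)
  fit_fun <- if (solver == "nonneg") cp_nonneg else cp_als
  subjects <- unique(tasks$subject)
  fits <- list()
  S <- dim(tensor)[1]
  w_walk <- matrix(NA_real_, length(subjects), S)
  w_run <- matrix(NA_real_, length(subjects), S)
  for (i in seq_along(subjects)) {
    rows <- which(tasks$subject == subjects[i])
    sub <- data_tensor(
      as_plain_array(tensor)[, , rows, drop = FALSE],
      channels = channel_labels(tensor),
      tasks = tasks[rows, ], nonneg = is_nonneg_tensor(tensor)
    )
    f <- fit_fun(sub, R,
      max_iter = config$max_iter, tol = config$tol,
      n_restarts = config$n_restarts, seed = config$seed + 100L + i
    )
    ct <- mode_discontinuity(f,
      walk_ref = config$walk_ref, run_ref = config$run_ref
    )
    sel <- ct$components[ct$components$selected, ]
    walk_comp <- sel$component[sel$dominance == "walk"]
    run_comp <- sel$component[sel$dominance == "run"]
    if (length(walk_comp) && length(run_comp)) {
      w_walk[i, ] <- f$spatial[, walk_comp[1]]
      w_run[i, ] <- f$spatial[, run_comp[1]]
    }
    fits[[i]] <- list(fit = f, contrast = ct)
  }
  ok <- stats::complete.cases(w_walk) & stats::complete.cases(w_run)
  if (sum(ok) < 2) {
    return(list(per_subject = fits, anova = NULL))
  }
  arr <- array(
    c(w_walk[ok, , drop = FALSE], w_run[ok, , drop = FALSE]),
    dim = c(sum(ok), S, 2),
    dimnames = list(
      paste0("s", subjects[ok]), channel_labels(tensor), c("walk", "run")
    )
  )
  list(
    per_subject = fits,
    anova = rm_anova_two_way(arr, alpha = config$alpha),
    weights_array = arr
  )
}

#' Write or read a CP model as JSON
#'
#' Stores the weights, the three factor matrices, flags, task descriptors
#' and (for fits) the diagnostics in a single JSON document; the round trip
#' restores the model to full double precision.
#'
#' @param m a `cp_model` or `cp_fit`.
#' @param path JSON file path.
#' @param extra named list of extra metadata.
#' @export
write_cp_model <- function(m, path, extra = list()) {
  stopifnot(inherits(m, "cp_model"))
  payload <- c(list(
    R = m$R, lambda = m$lambda,
    spatial = m$spatial, temporal = m$temporal, task = m$task,
    nonneg = m$nonneg, channels = m$channels,
    tasks = if (!is.null(m$tasks)) as.data.frame(m$tasks),
    diagnostics = m$diagnostics
  ), extra)
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  invisible(path)
}

#' @rdname write_cp_model
#' @export
read_cp_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- cp_model(
    p$lambda, p$spatial, p$temporal, p$task,
    nonneg = isTRUE(p$nonneg), normalize = FALSE,
    channels = p$channels,
    tasks = if (!is.null(p$tasks)) tibble::as_tibble(p$tasks)
  )
  if (!is.null(p$diagnostics)) {
    m$diagnostics <- p$diagnostics
    class(m) <- c("cp_fit", class(m))
  }
  m
}
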