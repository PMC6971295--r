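#' Cosine similarity (factor congruence)
#'
#' The congruence coefficient between two factor vectors: their inner
#' product divided by the product of their norms. Zero vectors give 0.
#'
#' @param a,b numeric vectors of equal length.
#' @return A scalar in `[-1, 1]`.
#' @export
congruence <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# all injective assignments of seq_len(k) into seq_len(n), k <= n
injections <- function(n, k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  rec <- function(chosen) {
    if (length(chosen) == k) {
      out[[length(out) + 1L]] <<- chosen
      return(invisible())
    }
    for (j in setdiff(seq_len(n), chosen)) rec(c(chosen, j))
  }
  rec(integer(0))
  out
}

#' Match the components of two CP models
#'
#' Finds the one-to-one assignment between the components of two models
#' that maximizes total congruence, where each pair's congruence is the
#' cosine of their concatenated factor vectors (by default spatial +
#' temporal; the task factor can be included when both models share tasks).
#' Solved exactly by exhaustive enumeration (ranks up to 8). When ranks
#' differ, the smaller model's components are matched into the larger one
#' and unmatched components are reported.
#'
#' @param model_a,model_b `cp_model`s with equal channel and frame counts.
#' @param weights_on which factors enter the congruence: any subset of
#'   `c("spatial", "temporal", "task")`.
#' @return A list of class `component_match`: `matches` (tibble with
#'   `component_a`, `component_b`, `congruence` and per-factor cosines),
#'   `total`, and `unmatched_b` indices.
#' @export
match_components <- function(model_a, model_b,
                             weights_on = c("spatial", "temporal")) {
  stopifnot(inherits(model_a, "cp_model"), inherits(model_b, "cp_model"))
  weights_on <- match.arg(weights_on,
    c("spatial", "temporal", "task"),
    several.ok = TRUE
  )
  Ra <- model_a$R
  Rb <- model_b$R
  if (Ra > Rb) {
    sw <- match_components(model_b, model_a, weights_on)
    sw$matches <- dplyr::rename(sw$matches,
      component_a = "component_b", component_b = "component_a"
    )[, c("component_a", "component_b", "congruence",
          "cos_spatial", "cos_temporal", "cos_task")]
    return(sw)
  }
  if (Rb > 8) stop("exhaustive matching supports rank <= 8", call. = FALSE)
  concat <- function(m, r) {
    unlist(lapply(weights_on, function(f) m[[f]][, r]))
  }
  C <- outer(seq_len(Ra), seq_len(Rb), Vectorize(function(i, j) {
    congruence(concat(model_a, i), concat(model_b, j))
  }))
  cands <- injections(Rb, Ra)
  totals <- vapply(cands, function(p) sum(C[cbind(seq_len(Ra), p)]),
    numeric(1)
  )
  best <- cands[[which.max(totals)]]
  fac_cos <- function(f, i, j) congruence(model_a[[f]][, i], model_b[[f]][, j])
  matches <- tibble::tibble(
    component_a = seq_len(Ra),
    component_b = best,
    congruence = C[cbind(seq_len(Ra), best)],
    cos_spatial = mapply(fac_cos, "spatial", seq_len(Ra), best),
    cos_temporal = mapply(fac_cos, "temporal", seq_len(Ra), best),
    cos_task = if (nrow(model_a$task) == nrow(model_b$task)) {
      mapply(fac_cos, "task", seq_len(Ra), best)
    } else {
      NA_real_
    }
  )
  structure(
    list(
      matches = matches, total = max(totals),
      unmatched_b = setdiff(seq_len(Rb), best)
    ),
    class = "component_match"
  )
}

#' @export
print.component_match <- function(x, ...) {
  cat("<component_match>\n")
  print(x$matches)
  invisible(x)
}

#' Score factor recovery against a planted ground truth
#'
#' Matches the estimated components to the planted ones and returns the
#' mean matched congruence, with per-component detail. A score of 1 means
#' perfect recovery (up to the permutation and sign indeterminacies of CP).
#'
#' @param estimated,truth `cp_model`s (typically a `cp_fit` and a
#'   `ground_truth`).
#' @param weights_on factors entering the congruence (default all three).
#' @return A list with `score` (mean congruence), `matches` (tibble) and
#'   `unmatched` truth components.
#' @export
recovery_score <- function(estimated, truth,
                           weights_on = c("spatial", "temporal", "task")) {
  m <- match_components(estimated, truth, weights_on = weights_on)
  list(score = mean(m$matches$congruence), matches = m$matches,
       unmatched = m$unmatched_b)
}

#' Walk-run discontinuity of the task-dependent modulations
#'
#' Ranks components by the absolute difference between their task
#' modulation at a walking reference speed (default 1.8 m/s) and at a
#' running reference speed (default 2.3 m/s), averaged across subjects. The
#' top two components are selected and labeled walk-dominant (modulation
#' larger at the walking reference) or run-dominant. When speeds are
#' binned, the bin containing each reference speed is used.
#'
#' @param model a `cp_model` whose `$tasks` describe subjects, speeds and
#'   modes (as produced by the generator or [assemble_tensor()]).
#' @param walk_ref,run_ref reference speeds in m/s.
#' @param tasks optional task descriptor tibble overriding `model$tasks`.
#' @return A list of class `mode_contrast`: `components` (tibble with
#'   `component`, `discontinuity`, `dominance`, `selected`), the reference
#'   speeds, and the per-subject task indices used.
#' @export
mode_discontinuity <- function(model, walk_ref = 1.8, run_ref = 2.3,
                               tasks = NULL) {
  stopifnot(inherits(model, "cp_model"))
  if (is.null(tasks)) tasks <- model$tasks
  if (is.null(tasks) || !all(c("subject", "speed") %in% names(tasks))) {
    stop("task descriptors with subject and speed required", call. = FALSE)
  }
  find_ref <- function(sub_rows, ref) {
    if (all(c("speed_lo", "speed_hi") %in% names(sub_rows))) {
      hit <- which(sub_rows$speed_lo <= ref & ref < sub_rows$speed_hi)
    } else {
      d <- abs(sub_rows$speed - ref)
      hit <- which(d == min(d) & d <= 0.15)
    }
    if (length(hit)) hit[1] else NA_integer_
  }
  subjects <- unique(tasks$subject)
  refs <- lapply(subjects, function(s) {
    rows <- which(tasks$subject == s)
    iw <- find_ref(tasks[rows, ], walk_ref)
    ir <- find_ref(tasks[rows, ], run_ref)
    if (is.na(iw) || is.na(ir)) {
      stop("missing reference speed for subject ", s, call. = FALSE)
    }
    c(walk = rows[iw], run = rows[ir])
  })
  kw <- vapply(refs, `[[`, integer(1), "walk")
  kr <- vapply(refs, `[[`, integer(1), "run")
  diff_wr <- vapply(seq_len(model$R), function(r) {
    mean(model$task[kw, r] - model$task[kr, r])
  }, numeric(1))
  disc <- vapply(seq_len(model$R), function(r) {
    mean(abs(model$task[kw, r] - model$task[kr, r]))
  }, numeric(1))
  ord <- order(disc, decreasing = TRUE)
  comp <- tibble::tibble(
    component = seq_len(model$R),
    discontinuity = disc,
    dominance = ifelse(diff_wr > 0, "walk", "run"),
    selected = seq_len(model$R) %in% ord[seq_len(min(2L, model$R))]
  )
  structure(
    list(
      components = comp, walk_ref = walk_ref, run_ref = run_ref,
      walk_tasks = kw, run_tasks = kr
    ),
    class = "mode_contrast"
  )
}

#' @export
print.mode_contrast <- function(x, ...) {
  cat(sprintf(
    "<mode_contrast> walk %.2f m/s vs run %.2f m/s\n", x$walk_ref, x$run_ref
  ))
  print(x$components)
  invisible(x)
}

#' Two-factor repeated-measures ANOVA with Tukey post hoc comparisons
#'
#' Within-subject ANOVA of spatial-module recruitment values with factors
#' muscle and movement mode (walking vs running): every subject contributes
#' one value per (muscle, mode) cell. The classical sums-of-squares
#' decomposition is used (each effect tested against its own
#' subject-by-effect interaction error term, no sphericity correction), so
#' with `M` muscles, 2 modes and `N` subjects the muscle-by-mode interaction
#' has `df = ((M-1), (N-1)(M-1))`. When the interaction is present, Tukey
#' comparisons of walking vs running are run per muscle using the
#' interaction error term and studentized-range quantiles with the full
#' `2M` interaction cell means as the family.
#'
#' @param weights either a long data frame with columns `subject`,
#'   `muscle`, `mode`, `weight`, or a 3-d array `subjects x muscles x modes`.
#' @param alpha significance level used to gate the post hoc test.
#' @return A list of class `rm_anova`: `table` (tibble with `effect`,
#'   `df1`, `df2`, `statistic`, `p.value`), `posthoc` (tibble with per-
#'   muscle walk/run means, difference, and Tukey-adjusted p), `ms_error`
#'   (interaction error mean square) and the design counts.
#' @export
rm_anova_two_way <- function(weights, alpha = 0.05) {
  long <- if (is.array(weights) && length(dim(weights)) == 3) {
    dn <- dimnames(weights)
    d <- dim(weights)
    expand.grid(
      subject = if (is.null(dn[[1]])) paste0("s", seq_len(d[1])) else dn[[1]],
      muscle = if (is.null(dn[[2]])) paste0("m", seq_len(d[2])) else dn[[2]],
      mode = if (is.null(dn[[3]])) c("walk", "run")[seq_len(d[3])] else dn[[3]],
      stringsAsFactors = FALSE
    ) |>
      dplyr::mutate(weight = as.numeric(weights))
  } else {
    as.data.frame(weights)
  }
  need <- c("subject", "muscle", "mode", "weight")
  if (!all(need %in% names(long))) {
    stop("weights must provide subject, muscle, mode, weight", call. = FALSE)
  }
  long$subject <- factor(long$subject)
  long$muscle <- factor(long$muscle)
  long$mode <- factor(long$mode)
  N <- nlevels(long$subject)
  M <- nlevels(long$muscle)
  n_modes <- nlevels(long$mode)
  counts <- table(long$subject, long$muscle, long$mode)
  if (any(counts != 1)) {
    stop("design must be complete and balanced: one value per cell",
      call. = FALSE
    )
  }
  fit <- stats::aov(
    weight ~ muscle * mode + Error(subject / (muscle * mode)),
    data = long
  )
  sm <- summary(fit)
  pull_effect <- function(stratum, term) {
    tab <- sm[[paste0("Error: ", stratum)]][[1]]
    i <- match(term, trimws(rownames(tab)))
    err <- nrow(tab) # residual row is last
    tibble::tibble(
      effect = term,
      df1 = tab[i, "Df"], df2 = tab[err, "Df"],
      statistic = tab[i, "F value"], p.value = tab[i, "Pr(>F)"],
      ms_error = tab[err, "Mean Sq"]
    )
  }
  table <- dplyr::bind_rows(
    pull_effect("subject:muscle", "muscle"),
    pull_effect("subject:mode", "mode"),
    pull_effect("subject:muscle:mode", "muscle:mode")
  )
  ms_err <- table$ms_error[table$effect == "muscle:mode"]
  df_err <- table$df2[table$effect == "muscle:mode"]
  cell <- long |>
    dplyr::group_by(.data$muscle, .data$mode) |>
    dplyr::summarise(mean = mean(.data$weight), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "mode", values_from = "mean")
  modes <- levels(long$mode)
  walk_col <- if ("walk" %in% modes) "walk" else modes[1]
  run_col <- setdiff(modes, walk_col)[1]
  se <- sqrt(ms_err / N)
  posthoc <- cell |>
    dplyr::mutate(
      mean_walk = .data[[walk_col]],
      mean_run = .data[[run_col]],
      diff = .data$mean_walk - .data$mean_run,
      q = abs(.data$diff) / se,
      p_adj = stats::ptukey(.data$q, nmeans = M * n_modes, df = df_err,
        lower.tail = FALSE
      )
    ) |>
    dplyr::select("muscle", "mean_walk", "mean_run", "diff", "q", "p_adj")
  interaction_p <- table$p.value[table$effect == "muscle:mode"]
  structure(
    list(
      table = dplyr::select(table, -"ms_error"),
      posthoc = posthoc,
      interaction_significant = is.finite(interaction_p) &&
        interaction_p < alpha,
      ms_error = ms_err, df_error = df_err,
      n_subjects = N, n_muscles = M, n_modes = n_modes
    ),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(
    "<rm_anova> %d subjects x %d muscles x %d modes\n",
    x$n_subjects, x$n_muscles, x$n_modes
  ))
  print(x$table)
  if (x$interaction_significant) {
    cat("muscle-by-mode interaction significant; Tukey comparisons:\n")
    print(x$posthoc)
  }
  invisible(x)
}
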