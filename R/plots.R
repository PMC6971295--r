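#' Plot the modules and task modulations of a CP model
#'
#' One column per component, three rows: spatial modules as bars over
#' channels, temporal modules as lines over the normalized gait cycle, and
#' task-dependent modulations as dots over speed (colored by walk/run mode
#' when the task descriptors carry it).
#'
#' @param object a `cp_model` or `cp_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cp_model
#' @export
autoplot.cp_model <- function(object, ...) {
  td <- tidy(object)
  td$panel <- factor(td$part, levels = c("spatial", "temporal", "task"))
  spatial <- td[td$part == "spatial", ]
  temporal <- td[td$part == "temporal", ]
  task <- td[td$part == "task", ]
  task$x <- if ("speed" %in% names(task) && !all(is.na(task$speed))) {
    task$speed
  } else {
    task$index
  }
  p <- ggplot2::ggplot() +
    ggplot2::geom_col(
      data = spatial,
      ggplot2::aes(x = .data$index, y = .data$value)
    ) +
    ggplot2::geom_line(
      data = temporal,
      ggplot2::aes(x = .data$index, y = .data$value)
    )
  if ("mode" %in% names(task) && !all(is.na(task$mode))) {
    p <- p + ggplot2::geom_point(
      data = task,
      ggplot2::aes(x = .data$x, y = .data$value, colour = .data$mode),
      size = 0.8
    )
  } else {
    p <- p + ggplot2::geom_point(
      data = task,
      ggplot2::aes(x = .data$x, y = .data$value), size = 0.8
    )
  }
  p +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$panel),
      cols = ggplot2::vars(.data$component),
      scales = "free"
    ) +
    ggplot2::labs(
      x = "channel / frame / speed", y = "factor value",
      title = "CP components: spatial, temporal, task modulation"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a rank-selection curve
#'
#' Variance accounted for against the number of components, with the
#' selection threshold drawn as a horizontal line and the selected rank
#' marked.
#'
#' @param selection the result of [select_rank()].
#' @return A ggplot object.
#' @export
plot_rank_curve <- function(selection) {
  curve <- selection$curve
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$R, y = .data$vaf)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      yintercept = selection$threshold, linetype = "dashed"
    ) +
    ggplot2::geom_vline(xintercept = selection$R, linetype = "dotted") +
    ggplot2::scale_x_continuous(breaks = curve$R) +
    ggplot2::labs(
      x = "number of components R", y = "variance accounted for",
      title = sprintf("Rank selection: R = %d", selection$R)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the walk-run discontinuity contrast
#'
#' Bar plot of the per-component discontinuity statistic, filled by
#' dominance label, with the selected top-2 components outlined.
#'
#' @param object a `mode_contrast`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot mode_contrast
#' @export
autoplot.mode_contrast <- function(object, ...) {
  comp <- object$components
  ggplot2::ggplot(comp, ggplot2::aes(
    x = factor(.data$component), y = .data$discontinuity,
    fill = .data$dominance, colour = .data$selected
  )) +
    ggplot2::geom_col(linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = NA)) +
    ggplot2::labs(
      x = "component",
      y = sprintf(
        "|t(%.1f m/s) - t(%.1f m/s)|", object$walk_ref, object$run_ref
      ),
      title = "Walk-run discontinuity of task modulations"
    ) +
    ggplot2::theme_minimal()
}
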