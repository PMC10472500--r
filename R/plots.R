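# autoplot() methods for the package's result classes. Each returns a
# ggplot object; no plot is drawn as a side effect.

#' Plot a recording
#'
#' Channel traces for one trial, offset vertically by channel position.
#'
#' @param object an [lfp_recording()] object.
#' @param trial trial index (default 1).
#' @param offset vertical offset between channels in signal units (default:
#'   3 x the median channel standard deviation).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot lfp_recording
#' @export
autoplot.lfp_recording <- function(object, trial = 1, offset = NULL, ...) {
  V <- object$data[trial, , ]
  offset <- offset %||% (3 * stats::median(apply(V, 1, stats::sd)))
  df <- tidyr::pivot_longer(
    tibble::as_tibble(t(V), .name_repair = ~paste0("ch", seq_along(.x))) |>
      dplyr::mutate(time_ms = (dplyr::row_number() - 1) * object$time_step_ms),
    -"time_ms", names_to = "channel", values_to = "value"
  ) |>
    dplyr::mutate(rank = as.integer(sub("ch", "", .data$channel)),
                  trace = .data$value + offset * .data$rank)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$trace,
                                   group = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "channel (offset traces)",
                  title = sprintf("Trial %d", trial)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot an extracellular field estimate
#'
#' Heat map of the extracellular potential over the patch and depth at one
#' time point.
#'
#' @param object a [field_estimate()] object.
#' @param time_index snapshot to show (default 1).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot field_estimate
#' @export
autoplot.field_estimate <- function(object, time_index = 1, ...) {
  df <- expand.grid(x_mm = object$x_grid, y_mm = object$y_grid)
  df$Ve <- as.vector(object$Ve[, , time_index])
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm, fill = .data$Ve)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "position (mm)", y = "distance from sheet (mm)",
                  fill = "V_e",
                  title = sprintf("Extracellular potential, snapshot %d", time_index)) +
    ggplot2::theme_minimal()
}

#' Plot spatial GC strengths over time
#'
#' Strength per snapshot with significant snapshots highlighted.
#'
#' @param object a `gc_result` from [gc_over_time()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot gc_result
#' @export
autoplot.gc_result <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(.data$snapshot, .data$strength,
                               colour = .data$significant)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "snapshot", y = "GC strength (log RSS ratio)",
                  colour = sprintf("p < %g", object$alpha),
                  title = sprintf("%s %s %s", object$direction[1], "→",
                                  object$direction[2])) +
    ggplot2::theme_minimal()
}

#' Plot a representational dissimilarity matrix
#'
#' @param object an [new_rdm()] object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot rdm
#' @export
autoplot.rdm <- function(object, ...) {
  m <- object$matrix
  df <- expand.grid(row = object$labels, col = object$labels)
  df$dissimilarity <- as.vector(m)
  df$row <- factor(df$row, levels = rev(object$labels))
  df$col <- factor(df$col, levels = object$labels)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$dissimilarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "1 - r",
                  title = "Representational dissimilarity") +
    ggplot2::theme_minimal()
}

#' Plot Bayes factors of a model comparison
#'
#' Held-out Bayes factors per trial, grouped by cue angle, with the +/- 3
#' decision band.
#'
#' @param object a `model_comparison` from [compare_models()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot model_comparison
#' @export
autoplot.model_comparison <- function(object, ...) {
  thr <- object$bf_threshold
  ggplot2::ggplot(object$bf_per_trial,
                  ggplot2::aes(factor(.data$cue_angle_deg), .data$bf)) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "firebrick",
                          size = 2.5) +
    ggplot2::labs(x = "cue angle (deg)",
                  y = "Bayes factor (non-ephaptic - ephaptic)",
                  title = sprintf("Winner: %s (mean BF %.2f)", object$winner,
                                  object$mean_bf)) +
    ggplot2::theme_minimal()
}
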