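#' Plot a probe track
#'
#' @param object A [probe_track()].
#' @param ... Unused.
#' @return A ggplot: score vs probe start, faceted by chromosome.
#' @exportS3Method ggplot2::autoplot
autoplot.probe_track <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$start, y = .data$score)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "enrichment (score units)") +
    ggplot2::theme_minimal()
}

#' Plot a delta-track histogram with calling thresholds
#'
#' Mirrors the genome-wide histogram check of the delta distribution:
#' near-normal, centred close to zero, with the `median +/- k_sd * sd`
#' calling thresholds marked.
#'
#' @param object A [delta_track()].
#' @param k_sd SD multiplier for the threshold lines (default 2).
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.delta_track <- function(object, k_sd = 2, bins = 100, ...) {
  ns <- null_stats(object)
  thr <- ns$median + c(-1, 1) * k_sd * ns$sd
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = NA) +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_vline(xintercept = ns$median, colour = "grey30") +
    ggplot2::labs(x = expression(Delta ~ "(score units)"), y = "probes",
                  subtitle = sprintf("median %.3g, sd %.3g, n = %d",
                                     ns$median, ns$sd, ns$n)) +
    ggplot2::theme_minimal()
}

#' Plot a 3C anchor interaction profile
#'
#' @param object An [interaction_profile()].
#' @param ... Unused.
#' @return A ggplot: normalized interaction frequency vs fragment
#'   midpoint, with standard-error bars; the anchor's self-ligation
#'   fragment is highlighted.
#' @exportS3Method ggplot2::autoplot
autoplot.interaction_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$midpoint,
                                       y = .data$interaction)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$interaction - ifelse(is.na(.data$se), 0, .data$se),
      ymax = .data$interaction + ifelse(is.na(.data$se), 0, .data$se),
      shape = .data$self_ligation)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 8),
                                guide = "none") +
    ggplot2::labs(x = "fragment midpoint (bp)",
                  y = "normalized interaction frequency") +
    ggplot2::theme_minimal()
}

#' Bar chart of category change percentages
#'
#' @param percentages Output of [category_percentages()].
#' @return A ggplot: %UP and %DOWN per group (and region, if present).
#' @export
plot_category_percentages <- function(percentages) {
  long <- percentages |>
    filter(!.data$empty_group) |>
    pivot_longer(c("pct_up", "pct_down"), names_to = "direction",
                 values_to = "pct") |>
    mutate(direction = ifelse(.data$direction == "pct_up", "UP", "DOWN"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$direction, y = .data$pct,
                                          fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = NULL, y = "% of genes") +
    ggplot2::theme_minimal()
  if ("region" %in% names(long)) p <- p + ggplot2::facet_wrap(~region)
  p
}

#' Boxplot of pause indices before/after depletion
#'
#' @param pause A tibble with columns `condition`, `pause_index`, `flag`
#'   (e.g. the `pause` element returned by [run_pipeline()]).
#' @return A ggplot with log-scaled pause index per condition.
#' @export
plot_pause_index <- function(pause) {
  ggplot2::ggplot(filter(pause, .data$flag == "ok"),
                  ggplot2::aes(x = .data$condition, y = .data$pause_index)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "pause index (promoter / body)") +
    ggplot2::theme_minimal()
}
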