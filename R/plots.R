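#' Plot clock predictions against true days in culture
#'
#' Scatter of predicted versus true days with the identity line, annotated
#' with the squared Pearson correlation — the standard way of showing an
#' epigenetic clock's fit.
#'
#' @param predicted numeric predictions (or a [predict_days()] tibble).
#' @param truth true days, aligned with `predicted`.
#' @return a ggplot object.
#' @export
plot_clock_fit <- function(predicted, truth) {
  if (is.data.frame(predicted)) predicted <- predicted$predicted_days
  ev <- evaluate_clock(predicted, truth)
  df <- tibble::tibble(truth = as.numeric(truth), predicted = as.numeric(predicted))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(colour = "#2166ac", alpha = 0.8) +
    ggplot2::labs(
      x = "days in culture", y = "predicted days",
      title = sprintf("Epigenetic clock fit (r² = %.2f, RMSE = %.1f d)",
                      ev$r_squared, ev$rmse)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a per-CpG Cox screen as HR versus p-value
#'
#' Scatter of the adjusted hazard ratio (per 10% DNAm) against the Wald
#' p-value on a -log10 scale, with the selection thresholds drawn in.
#'
#' @param table result of [cox_screen_cpgs()].
#' @param hr_min,p_max thresholds to draw (defaults as in
#'   [select_survival_cpgs()]).
#' @return a ggplot object.
#' @export
plot_cox_screen <- function(table, hr_min = 1.0, p_max = 0.01) {
  df <- dplyr::filter(table, !is.na(.data$hr), !is.na(.data$p_value))
  df$selected <- df$hr > hr_min & df$p_value < p_max
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hr, y = -log10(.data$p_value),
                                   colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = hr_min, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = -log10(p_max), linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#b2182b"),
                                 guide = "none") +
    ggplot2::labs(x = "hazard ratio per 10% DNAm", y = "-log10 Wald p",
                  title = "Per-CpG Cox screen") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for a stratified score
#'
#' @param object a `km_strata` from [km_stratify()].
#' @param ... unused.
#' @return a ggplot object (step curves per group, log-rank p in title).
#' @export
autoplot.km_strata <- function(object, ...) {
  start <- dplyr::distinct(object$curves, .data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  df <- dplyr::bind_rows(
    start,
    dplyr::select(object$curves, "group", "time", "survival")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "overall survival",
                  colour = NULL,
                  title = sprintf("Kaplan-Meier (log-rank p = %.3g)",
                                  object$logrank_p)) +
    ggplot2::theme_minimal()
}

#' Heatmap-style plot of per-read methylation calls
#'
#' Visualises the sequence of methylated and unmethylated CpGs within
#' individual reads of one amplicon, the read-level view in which stochastic
#' drift appears as salt-and-pepper rather than blockwise patterns.
#'
#' @param rs a [read_set()].
#' @param max_reads downsample to at most this many reads for display.
#' @return a ggplot object.
#' @export
plot_read_patterns <- function(rs, max_reads = 100L) {
  stopifnot(inherits(rs, "read_set"))
  calls <- rs$calls
  if (nrow(calls) > max_reads) calls <- calls[seq_len(max_reads), , drop = FALSE]
  df <- tibble::as_tibble(calls, .name_repair = "minimal") |>
    dplyr::mutate(read = dplyr::row_number()) |>
    tidyr::pivot_longer(-"read", names_to = "position", values_to = "call") |>
    dplyr::mutate(position = as.numeric(.data$position))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$position), y = .data$read,
                                   fill = factor(.data$call))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "#f7f7f7", `1` = "#b2182b"),
                               na.value = "grey80", name = "methylated") +
    ggplot2::labs(x = "CpG position", y = "read",
                  title = sprintf("%s (%s)", rs$amplicon_id, rs$sample_id)) +
    ggplot2::theme_minimal()
}
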