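group_palette <- c(whole = "black", high = "red3", low = "royalblue3",
                   mid = "grey55")

#' Plot group-averaged normalized destaining traces
#'
#' Mean ± SEM normalized FM fluorescence over time for the whole population
#' and the high/low immunoreactivity populations — the standard
#' group-segregated kinetics figure.
#'
#' @param summary A `group_summary` from [summarize_groups()].
#' @return A ggplot object.
#' @export
plot_group_traces <- function(summary) {
  stopifnot(inherits(summary, "group_summary"))
  tr <- summary$traces
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s, y = .data$mean,
                                   colour = .data$group,
                                   fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_colour_manual(values = group_palette) +
    ggplot2::scale_fill_manual(values = group_palette) +
    ggplot2::labs(x = "time (s)", y = "normalized FM fluorescence (F/F0)",
                  colour = "population", fill = "population") +
    ggplot2::theme_classic()
}

#' Bar chart of mean unloaded fractions by population
#'
#' @param summary A `group_summary` from [summarize_groups()].
#' @return A ggplot object.
#' @export
plot_unloaded_fractions <- function(summary) {
  stopifnot(inherits(summary, "group_summary"))
  g <- dplyr::filter(summary$groups, .data$n > 0)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$group,
                                  y = .data$mean_unloaded_pct,
                                  fill = .data$group)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_unloaded_pct - .data$sem_unloaded_pct,
                   ymax = .data$mean_unloaded_pct + .data$sem_unloaded_pct),
      width = 0.15) +
    ggplot2::scale_fill_manual(values = group_palette, guide = "none") +
    ggplot2::labs(x = "population", y = "unloaded fraction (%)") +
    ggplot2::theme_classic()
}

#' Scatter of normalized channel-2 vs channel-1 immunoreactivity
#'
#' The two-channel linearity control: per-ROI normalized IR of the second
#' channel against the first with the fitted regression line. A slope near
#' 1 and strong positive correlation validate the experiment.
#'
#' @param ir An [ir_table()] with two channels.
#' @param channels Character pair naming the channels (defaults to the
#'   first two found in the table).
#' @return A ggplot object.
#' @export
plot_channel_linearity <- function(ir, channels = NULL) {
  norm_cols <- grep("_norm_ir$", names(ir), value = TRUE)
  if (is.null(channels)) {
    stopifnot(length(norm_cols) >= 2)
    channels <- sub("_norm_ir$", "", norm_cols[1:2])
  }
  a <- ir[[paste0(channels[1], "_norm_ir")]]
  b <- ir[[paste0(channels[2], "_norm_ir")]]
  df <- tibble::tibble(a = a, b = b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red3", linewidth = 0.6) +
    ggplot2::labs(x = paste(channels[1], "normalized IR"),
                  y = paste(channels[2], "normalized IR")) +
    ggplot2::theme_classic()
}

#' @rdname plot_group_traces
#' @param object A `group_summary`.
#' @param ... Unused.
#' @export
autoplot.group_summary <- function(object, ...) {
  plot_group_traces(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
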