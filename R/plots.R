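# ggplot2 visualizations for each result type.

#' Plot kinematic trials as line panels
#'
#' One facet per channel, one line per trial; real and synthetic trials can
#' be overlaid by color.
#'
#' @param dataset A `trial_dataset`.
#' @param channels Channel names to show (default all 9).
#' @param max_trials Cap on the number of trials drawn.
#' @return A ggplot object.
#' @export
plot_trials <- function(dataset, channels = .CHANNEL_NAMES,
                        max_trials = 30L) {
  ds <- head(as_tibble(dataset), max_trials)
  long <- purrr::map_dfr(seq_len(nrow(ds)), function(i) {
    s <- ds$signal[[i]][, channels, drop = FALSE]
    tibble(
      trial = i, provenance = ds$provenance[i], task = ds$task[i],
      time = rep((seq_len(nrow(s)) - 1) / .SAMPLE_RATE, length(channels)),
      channel = rep(channels, each = nrow(s)),
      value = as.numeric(s)
    )
  })
  long$channel <- factor(long$channel, levels = .CHANNEL_NAMES)
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     group = .data$trial,
                                     colour = .data$provenance)) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "cm / rad") +
    ggplot2::theme_minimal()
}

#' @describeIn tsne_embed Scatter plot of the embedding: color = task,
#'   shape = impairment group, open symbols = synthetic.
#' @param object A `tsne_embedding`.
#' @param ... Unused.
#' @export
autoplot.tsne_embedding <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$dim1, .data$dim2,
                                       colour = .data$task,
                                       shape = .data$group,
                                       alpha = .data$provenance)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_alpha_manual(values = c(real = 1, synthetic = 0.35)) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::theme_minimal()
}

#' @describeIn rom_table Heat map of the p-value grid, tasks by rows and
#'   channels by columns, faceted by impairment group; cells below 0.05 are
#'   outlined.
#' @param object A `rom_table`.
#' @param ... Unused.
#' @export
autoplot.rom_table <- function(object, ...) {
  df <- as_tibble(object)
  df$significant <- !is.na(df$p_value) & df$p_value < 0.05
  ggplot2::ggplot(df, ggplot2::aes(.data$channel, .data$task,
                                   fill = .data$p_value)) +
    ggplot2::geom_tile(ggplot2::aes(colour = .data$significant),
                       linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black",
                                            `FALSE` = NA)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey80") +
    ggplot2::facet_wrap(~group) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @describeIn predict_confusion Row-percentage heat map of a confusion
#'   matrix.
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$prop)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(100 * .data$prop)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(fill = "row %") +
    ggplot2::theme_minimal()
}

#' @describeIn train_cgan Per-epoch loss curves of a trained bundle.
#' @param object A `gan_bundle`.
#' @param ... Unused.
#' @export
autoplot.gan_bundle <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$epoch, .data$value,
                                             colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "loss") +
    ggplot2::theme_minimal()
}

#' @describeIn run_experiment Mean ± SD bars per condition and metric.
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$mean,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(0.9), width = 0.3
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "score") +
    ggplot2::theme_minimal()
}
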