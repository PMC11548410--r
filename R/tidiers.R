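# broom-style tidiers for fitted objects.

#' Tidy a trained GAN bundle
#'
#' @param x A `gan_bundle`.
#' @param ... Unused.
#' @return Long tibble of per-epoch losses: `epoch`, `loss` (one of
#'   `d_loss`, `g_adv`, `g_spec`), `value`.
#' @export
tidy.gan_bundle <- function(x, ...) {
  tidyr::pivot_longer(x$history, cols = -"epoch",
                      names_to = "loss", values_to = "value")
}

#' One-row summary of a trained GAN bundle
#'
#' @param x A `gan_bundle`.
#' @param ... Unused.
#' @return Tibble with training size, class coverage, final losses, and the
#'   spectral weight.
#' @export
glance.gan_bundle <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  tibble(
    n_train = x$n_train,
    n_classes_trained = length(x$trained_classes),
    epochs = x$train_config$epochs,
    spectral_weight = x$train_config$spectral_weight,
    final_d_loss = h$d_loss,
    final_g_adv = h$g_adv,
    final_g_spec = h$g_spec
  )
}

#' @export
print.gan_bundle <- function(x, ...) {
  cat(sprintf(
    "<gan_bundle: %d trials, %d/%d classes, %d epochs, lambda_spec=%g>\n",
    x$n_train, length(x$trained_classes), x$gen_config$n_classes,
    x$train_config$epochs, x$train_config$spectral_weight))
  invisible(x)
}

#' Tidy a trained FCN model
#'
#' @param x An `fcn_model`.
#' @param ... Unused.
#' @return The per-epoch training history tibble.
#' @export
tidy.fcn_model <- function(x, ...) x$history

#' One-row summary of a trained FCN model
#'
#' @param x An `fcn_model`.
#' @param ... Unused.
#' @return Tibble with architecture sizes and final training loss/accuracy.
#' @export
glance.fcn_model <- function(x, ...) {
  n_par <- sum(vapply(x$net$layers, function(l) {
    if (is.null(l$params)) 0 else sum(vapply(l$params, length, numeric(1)))
  }, numeric(1)))
  h <- if (nrow(x$history)) x$history[nrow(x$history), ] else
    tibble(loss = NA_real_, accuracy = NA_real_)
  tibble(
    n_classes = x$config$n_classes, target = x$config$target,
    n_parameters = n_par, epochs = nrow(x$history),
    final_loss = h$loss, final_accuracy = h$accuracy
  )
}

#' Tidy a confusion matrix
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return Long tibble: `truth`, `predicted`, `n`, `prop` (row-normalized).
#' @export
tidy.confusion_matrix <- function(x, ...) {
  cm <- unclass(x)
  df <- as_tibble(as.table(cm), .name_repair = "minimal")
  names(df) <- c("truth", "predicted", "n")
  rs <- rowSums(cm)[df$truth]
  df$prop <- ifelse(rs > 0, df$n / rs, 0)
  df
}

#' Tidy a metrics report
#'
#' @param x A `metrics_report` from [run_experiment()].
#' @param ... Unused.
#' @return The per-condition mean ± SD tibble (the report itself, as a plain
#'   tibble).
#' @export
tidy.metrics_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "metrics_report")
  attr(out, "folds") <- NULL
  attr(out, "confusions") <- NULL
  out
}

#' One-row-per-condition summary of a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Wide tibble: one row per condition, `<metric>_mean` and
#'   `<metric>_sd` columns — a report-table layout.
#' @export
glance.metrics_report <- function(x, ...) {
  tidyr::pivot_wider(tidy(x), names_from = "metric",
                     values_from = c("mean", "sd"),
                     names_glue = "{metric}_{.value}")
}
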