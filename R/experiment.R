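# Five-fold cross-validated ratio-sweep experiment: real-only training vs
# four real:synthetic mixtures, always tested on held-out real trials.

#' Parse a real:synthetic augmentation ratio
#'
#' @param spec `"real"` (or `"Real Only"`), or a string `"a:b"` with coprime
#'   integer parts, e.g. `"2:3"` for 3 synthetic trials per 2 real.
#' @return An `aug_ratio` list with `real_part`, `synth_part`, `label`.
#' @examples
#' aug_ratio("1:2")
#' @export
aug_ratio <- function(spec) {
  if (inherits(spec, "aug_ratio")) return(spec)
  s <- tolower(gsub(" ", "", spec))
  if (s %in% c("real", "realonly", "real_only")) {
    return(structure(list(real_part = 1L, synth_part = 0L,
                          label = "Real Only"), class = "aug_ratio"))
  }
  parts <- suppressWarnings(as.integer(strsplit(s, ":")[[1]]))
  if (length(parts) != 2L || any(is.na(parts)) || parts[1] <= 0L ||
      parts[2] < 0L) {
    abort(paste0("Cannot parse ratio: ", spec),
          class = "reachsynth_invalid_input")
  }
  label <- if (parts[2] == 0L) "Real Only" else paste0(parts[1], ":", parts[2])
  structure(list(real_part = parts[1], synth_part = parts[2], label = label),
            class = "aug_ratio")
}

#' Number of synthetic trials implied by a ratio
#'
#' @param n_real_train Number of real training trials.
#' @param ratio An [aug_ratio()] or parseable string.
#' @return `round(n_real_train * synth_part / real_part)`; 0 for Real Only.
#' @examples
#' synth_count(100, "2:3")  # 150
#' @export
synth_count <- function(n_real_train, ratio) {
  r <- aug_ratio(ratio)
  if (r$real_part <= 0L) {
    abort("real_part must be positive.", class = "reachsynth_invalid_input")
  }
  if (n_real_train < 0) {
    abort("n_real_train must be nonnegative.",
          class = "reachsynth_invalid_input")
  }
  as.integer(round(n_real_train * r$synth_part / r$real_part))
}

#' Stratified k-fold partition
#'
#' Shuffles each class and deals its members round-robin across folds (with a
#' rotating offset), so per-class fold counts differ by at most one and the
#' folds partition all indices. Classes with fewer than `k` members trigger a
#' warning (they cannot appear in every fold).
#'
#' @param labels Vector of class labels, one per sample.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return A `fold_split`: list of `k` disjoint integer index vectors whose
#'   union is `seq_along(labels)`.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  if (n == 0L) {
    abort("labels must be nonempty.", class = "reachsynth_invalid_input")
  }
  k <- as.integer(k)
  set.seed(as.integer(seed))
  small <- names(which(table(labels) < k))
  if (length(small)) {
    warn(sprintf("Class(es) with fewer than %d samples: %s", k,
                 paste(small, collapse = ", ")))
  }
  folds <- vector("list", k)
  offset <- 0L
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    assign_to <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    for (f in seq_len(k)) {
      folds[[f]] <- c(folds[[f]], idx[assign_to == f])
    }
    offset <- (offset + length(idx)) %% k
  }
  folds <- lapply(folds, sort)
  structure(folds, class = "fold_split", n = n)
}

# Largest-remainder allocation of `total` across classes proportionally to
# `counts` (named integer vector).
allocate_proportional <- function(counts, total) {
  if (total == 0L) return(setNames(rep(0L, length(counts)), names(counts)))
  quota <- counts / sum(counts) * total
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(counts))
}

#' Augment a real training set with filtered synthetic trials
#'
#' Draws `synth_count(nrow(real_train), ratio)` synthetic trials from the
#' trained bundle, allocated across classes proportionally to the real class
#' counts (largest-remainder rounding), applies the 2 Hz post-filter, and
#' appends them to the real training set.
#'
#' @param real_train A `trial_dataset` of real training trials.
#' @param bundle A `gan_bundle` covering every class present in `real_train`.
#' @param ratio An [aug_ratio()] or string.
#' @param seed Integer seed for the generator noise.
#' @param filter Apply [lowpass_2hz()] to the synthetic trials (default TRUE).
#' @return A `trial_dataset` of size `nrow(real_train) + synth_count(...)`.
#' @export
augment_training_set <- function(real_train, bundle, ratio, seed = 1,
                                 filter = TRUE) {
  r <- aug_ratio(ratio)
  n_synth <- synth_count(nrow(real_train), r)
  if (n_synth == 0L) return(real_train)
  counts <- table(real_train$class)
  missing_cl <- setdiff(as.integer(names(counts)), bundle$trained_classes)
  if (length(missing_cl)) {
    abort(paste0("Bundle does not cover class(es): ",
                 paste(missing_cl, collapse = ", ")),
          class = "reachsynth_invalid_input")
  }
  alloc <- allocate_proportional(as.integer(counts), n_synth)
  cls <- rep(as.integer(names(counts)), alloc)
  synth <- sample_trials(bundle, cls, n = length(cls), seed = seed)
  if (filter) synth <- lowpass_2hz(synth)
  out <- bind_rows(as_tibble(real_train), as_tibble(synth))
  as_trial_dataset(out)
}

#' Classification metrics from a confusion matrix
#'
#' Per-class precision, recall and F1 are combined by support-weighted
#' averaging; accuracy is trace over total. Support-weighted recall equals
#' accuracy identically (each class contributes `n_i * (c_ii / n_i) / N`).
#' Classes with no predicted instances get precision 0 and are flagged.
#'
#' @param confusion Square nonnegative count matrix, rows = truth.
#' @return A one-row tibble: `precision`, `recall`, `f1`, `accuracy`,
#'   `n_zero_pred` (count of classes never predicted).
#' @examples
#' compute_metrics(matrix(c(8, 3, 2, 7), 2))
#' @export
compute_metrics <- function(confusion) {
  cm <- unclass(confusion)
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || any(cm < 0) ||
      sum(cm) == 0) {
    abort("confusion must be a nonzero square nonnegative matrix.",
          class = "reachsynth_invalid_input")
  }
  support <- rowSums(cm)
  predicted <- colSums(cm)
  correct <- diag(cm)
  total <- sum(cm)
  prec_c <- ifelse(predicted > 0, correct / predicted, 0)
  rec_c <- ifelse(support > 0, correct / support, 0)
  f1_c <- ifelse(prec_c + rec_c > 0,
                 2 * prec_c * rec_c / (prec_c + rec_c), 0)
  w <- support / total
  tibble(
    precision = sum(w * prec_c),
    recall = sum(w * rec_c),
    f1 = sum(w * f1_c),
    accuracy = sum(correct) / total,
    n_zero_pred = sum(predicted == 0 & support > 0)
  )
}

#' Cross-validated augmentation ratio sweep
#'
#' For each fold of a stratified k-fold split of the real dataset: train the
#' conditional GAN on the real training portion only (held-out trials never
#' reach the GAN), then for every ratio condition augment the training set,
#' train the FCN classifier, and evaluate on the held-out real fold.
#' Per-condition metrics are aggregated as mean and SD across folds. The
#' same per-fold GAN bundle is reused across ratio conditions for
#' comparability.
#'
#' @param real_dataset A `trial_dataset` of real trials.
#' @param gan_train_config,gen_config GAN configs (seeds are re-derived per
#'   fold from `seed`).
#' @param fcn_cfg An [fcn_config()].
#' @param ratios Character vector of conditions (default the full sweep
#'   `real, 2:1, 1:1, 2:3, 1:2`).
#' @param k Number of folds (default 5).
#' @param seed Master integer seed; folds, GAN training, sampling and
#'   classifier training all derive their seeds from it.
#' @param gan_global If `TRUE`, train one GAN on the full real dataset
#'   instead of per fold. This leaks held-out trials into the augmented
#'   training sets and exists only to mimic protocols that do not isolate
#'   the GAN per fold; the default (`FALSE`) is the leakage-safe protocol.
#' @return A `metrics_report`: tibble of per-condition mean ± SD for
#'   precision, recall, F1 and accuracy, with per-fold raw metrics in
#'   `attr(, "folds")` and Real Only / 1:1 confusion matrices in
#'   `attr(, "confusions")`.
#' @export
run_experiment <- function(real_dataset,
                           gan_train_config = gan_train_config(),
                           gen_config = generator_config(),
                           fcn_cfg = fcn_config(),
                           ratios = c("real", "2:1", "1:1", "2:3", "1:2"),
                           k = 5L, seed = 1L, gan_global = FALSE) {
  validate_trials(real_dataset)
  if (!all(real_dataset$provenance == "real")) {
    abort("run_experiment expects real-provenance trials only.",
          class = "reachsynth_invalid_input")
  }
  ratios <- lapply(ratios, aug_ratio)
  seed <- as.integer(seed)
  folds <- stratified_folds(real_dataset$class, k = k, seed = seed)
  global_bundle <- NULL
  if (gan_global) {
    gtc <- gan_train_config; gtc$seed <- (seed * 7L + 13L) %% 2147483647L
    global_bundle <- train_cgan(real_dataset, gtc, gen_config)
  }
  fold_rows <- list()
  confusions <- list()
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train_ds <- as_trial_dataset(
      as_tibble(real_dataset)[-test_idx, , drop = FALSE])
    test_ds <- as_trial_dataset(
      as_tibble(real_dataset)[test_idx, , drop = FALSE])
    stopifnot(all(test_ds$provenance == "real"))
    bundle <- if (gan_global) {
      global_bundle
    } else {
      gtc <- gan_train_config
      gtc$seed <- (seed * 1009L + f * 101L) %% 2147483647L
      train_cgan(train_ds, gtc, gen_config)
    }
    for (r in ratios) {
      aug <- augment_training_set(
        train_ds, bundle, r,
        seed = (seed * 2003L + f * 211L + r$synth_part * 17L +
                  r$real_part) %% 2147483647L
      )
      fc <- fcn_cfg
      fc$seed <- (seed * 3001L + f * 307L + r$synth_part * 19L +
                    r$real_part) %% 2147483647L
      model <- train_classifier(aug, fc)
      cm <- predict_confusion(model, test_ds)
      m <- compute_metrics(cm)
      m$condition <- r$label
      m$fold <- f
      m$n_train_real <- nrow(train_ds)
      m$n_train_synth <- nrow(aug) - nrow(train_ds)
      fold_rows[[length(fold_rows) + 1L]] <- m
      if (r$label %in% c("Real Only", "1:1")) {
        confusions[[paste(r$label, "fold", f)]] <- cm
      }
    }
  }
  per_fold <- bind_rows(fold_rows)
  long <- tidyr::pivot_longer(
    per_fold, cols = c("precision", "recall", "f1", "accuracy"),
    names_to = "metric", values_to = "value"
  )
  report <- long %>%
    group_by(.data$condition, .data$metric) %>%
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              .groups = "drop")
  cond_levels <- vapply(ratios, `[[`, character(1), "label")
  report$condition <- factor(report$condition, levels = cond_levels)
  report$metric <- factor(report$metric,
                          levels = c("precision", "recall", "f1", "accuracy"))
  report <- arrange(report, .data$condition, .data$metric)
  attr(report, "folds") <- per_fold
  attr(report, "confusions") <- confusions
  attr(report, "seed") <- seed
  attr(report, "k") <- k
  class(report) <- c("metrics_report", class(report))
  report
}
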