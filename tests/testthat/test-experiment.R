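test_that("augmentation ratios parse and imply exact synthetic counts", {
  expect_equal(synth_count(100, "real"), 0L)
  expect_equal(synth_count(100, "2:1"), 50L)
  expect_equal(synth_count(100, "1:1"), 100L)
  expect_equal(synth_count(100, "2:3"), 150L)
  expect_equal(synth_count(100, "1:2"), 200L)
  expect_identical(aug_ratio("Real Only")$synth_part, 0L)
  expect_error(aug_ratio("0:1"), class = "reachsynth_invalid_input")
  expect_error(synth_count(-1, "1:1"), class = "reachsynth_invalid_input")
})

test_that("stratified folds partition, balance, and reproduce", {
  labels <- rep(0:9, each = 10)          # 100 samples, 10 per class
  f <- stratified_folds(labels, k = 5, seed = 3)
  expect_length(f, 5L)
  all_idx <- sort(unlist(f))
  expect_identical(all_idx, seq_along(labels))          # cover, disjoint
  for (fold in f) {
    expect_equal(as.integer(table(labels[fold])), rep(2L, 10))
  }
  f2 <- stratified_folds(labels, k = 5, seed = 3)
  expect_identical(f, f2)
  f3 <- stratified_folds(labels, k = 5, seed = 4)
  expect_false(identical(f, f3))
  # uneven classes stay within +/- 1 per fold
  lab2 <- rep(0:2, times = c(7, 11, 13))
  f4 <- stratified_folds(lab2, k = 5, seed = 5)
  for (cl in 0:2) {
    per_fold <- vapply(f4, function(idx) sum(lab2[idx] == cl), integer(1))
    expect_lte(diff(range(per_fold)), 1L)
  }
  expect_warning(stratified_folds(c(0, 0, 1), k = 5, seed = 1),
                 "fewer than")
  expect_error(stratified_folds(integer(0)),
               class = "reachsynth_invalid_input")
})

test_that("metrics match hand computation and weighted recall equals accuracy", {
  perfect <- diag(c(5L, 7L, 9L))
  m <- compute_metrics(perfect)
  expect_equal(unlist(m[c("precision", "recall", "f1", "accuracy")]),
               c(precision = 1, recall = 1, f1 = 1, accuracy = 1))

  cm <- matrix(c(8L, 3L, 2L, 7L), 2)       # rows = truth
  m2 <- compute_metrics(cm)
  expect_equal(m2$accuracy, 0.75)
  expect_equal(m2$recall, 0.75)
  expect_equal(m2$precision, (10 * 8 / 11 + 10 * 7 / 9) / 20,
               tolerance = 1e-12)

  set.seed(8)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    r <- matrix(rpois(k * k, 3), k, k)
    if (sum(r) == 0 || any(rowSums(r) == 0)) next
    mm <- compute_metrics(r)
    expect_equal(mm$recall, mm$accuracy, tolerance = 1e-12)
  }
  expect_error(compute_metrics(matrix(0L, 3, 3)),
               class = "reachsynth_invalid_input")
})

test_that("augmentation allocates synthetic trials proportionally per class", {
  # 3-class dataset, 30 trials each
  ds <- toy_sine_dataset(30, freqs = c(0.5, 1), seed = 41)
  third <- toy_sine_dataset(30, freqs = c(0.75, 0.75), seed = 42)
  third <- as_trial_dataset(dplyr::mutate(
    tibble::as_tibble(third)[1:30, ], task = task_ids()[3]))
  ds90 <- as_trial_dataset(dplyr::bind_rows(tibble::as_tibble(ds),
                                            tibble::as_tibble(third)))
  ds90$provenance <- "real"
  suppressWarnings(
    bundle <- train_cgan(ds90, toy_train_config(epochs = 2, seed = 3),
                         toy_gen_config())
  )
  expect_identical(augment_training_set(ds90, bundle, "real"), ds90)
  aug <- augment_training_set(ds90, bundle, "1:2", seed = 4)
  expect_equal(nrow(aug), 90L + 180L)
  synth <- dplyr::filter(tibble::as_tibble(aug), provenance == "synthetic")
  expect_equal(as.integer(table(synth$class)), rep(60L, 3))
  # synthetic trials were lowpass filtered before joining
  raw <- sample_trials(bundle, synth$class[1], n = 20, seed = 4)
  expect_lt(highband_power_ratio(as_trial_dataset(synth)),
            max(highband_power_ratio(raw), 0.02))
})

test_that("run_experiment keeps protocol shape and never leaks synthetic trials", {
  ds <- simulate_dataset(2, seed = 71)
  g <- generator_config(noise_dim = 8L, reshape_channels = 6L,
                        block_filters = c(8L, 6L), kernel_size = 9L,
                        embed_dim = 4L)
  tc <- gan_train_config(epochs = 2L, batch_size = 16L, seed = 3L,
                         disc_filters = c(6L, 8L))
  fc <- fcn_config(conv_filters = c(4L, 8L), epochs = 2L)
  rep1 <- suppressWarnings(
    run_experiment(ds, tc, g, fc, ratios = c("real", "1:1"), k = 5,
                   seed = 11)
  )
  expect_s3_class(rep1, "metrics_report")
  expect_equal(nrow(tidy(rep1)), 2L * 4L)        # 2 conditions x 4 metrics
  folds <- attr(rep1, "folds")
  expect_equal(nrow(folds), 10L)                 # 5 folds x 2 conditions
  expect_true(all(folds$n_train_real == 48L))
  expect_equal(folds$n_train_synth[folds$condition == "1:1"], rep(48L, 5))
  expect_equal(folds$n_train_synth[folds$condition == "Real Only"],
               rep(0L, 5))
  expect_true(all(tidy(rep1)$mean >= 0 & tidy(rep1)$mean <= 1))
  # synthetic trials are rejected up front as experiment input
  synth_ds <- ds
  synth_ds$provenance <- "synthetic"
  expect_error(run_experiment(synth_ds, tc, g, fc, k = 2, seed = 1),
               class = "reachsynth_invalid_input")
})
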