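test_that("FCN forward pass yields normalized probabilities and exact parameter count", {
  cfg <- fcn_config(epochs = 1L, seed = 3)        # reference sizes: 64/128/k3
  model <- build_fcn(cfg)
  ds <- simulate_dataset(1, seed = 9)
  probs <- predict(model, ds, type = "prob")
  expect_equal(dim(probs), c(30L, 10L))
  expect_equal(rowSums(probs), rep(1, 30), tolerance = 1e-6)
  # with same padding the flatten width is 75 * 128 = 9600, so the first
  # dense layer holds 9600 * 100 + 100 = 960,100 parameters
  dense1 <- model$net$layers[[8]]
  expect_equal(length(dense1$params$W) + length(dense1$params$b), 960100L)
  # identical seeds give identical initializations
  m2 <- build_fcn(cfg)
  expect_identical(model$net$layers[[1]]$params$W,
                   m2$net$layers[[1]]$params$W)
})

test_that("forward pass is permutation-equivariant over the batch", {
  cfg <- fcn_config(conv_filters = c(4L, 8L), epochs = 1L, seed = 4)
  model <- build_fcn(cfg)
  ds <- simulate_dataset(1, seed = 10)
  probs <- predict(model, ds, type = "prob")
  perm <- sample.int(nrow(ds))
  ds_perm <- as_trial_dataset(tibble::as_tibble(ds)[perm, ])
  probs_perm <- predict(model, ds_perm, type = "prob")
  expect_equal(probs_perm, probs[perm, ], tolerance = 1e-12)
})

test_that("training learns separable simulator tasks and logs per epoch", {
  ds <- simulate_dataset(8, seed = 11)
  cfg <- small_fcn_config(epochs = 2L, seed = 5)
  model <- train_classifier(ds, cfg)
  expect_equal(nrow(model$history), 2L)
  expect_true(all(is.finite(model$history$loss)))

  cfg25 <- small_fcn_config(epochs = 25L, seed = 5)
  m25 <- train_classifier(ds, cfg25)
  expect_gt(dplyr::last(m25$history$accuracy), 0.9)
})

test_that("label-shuffled training collapses to chance-level held-out accuracy", {
  ds <- simulate_dataset(8, seed = 12)
  shuffled <- ds
  set.seed(1)
  shuffled$task <- sample(shuffled$task)
  shuffled$class <- encode_class(match(shuffled$task, task_ids()) - 1L,
                                 match(shuffled$group,
                                       impairment_groups()) - 1L)
  model <- train_classifier(shuffled, small_fcn_config(epochs = 4L, seed = 6))
  test <- simulate_dataset(3, seed = 13)
  acc <- compute_metrics(predict_confusion(model, test))$accuracy
  expect_lt(abs(acc - 0.1), 0.1)
})

test_that("confusion matrices conserve counts and normalize by row", {
  ds <- simulate_dataset(4, seed = 14)
  model <- train_classifier(ds, small_fcn_config(epochs = 3L, seed = 7))
  cm <- predict_confusion(model, ds)
  expect_equal(sum(cm), nrow(ds))
  td <- tidy(cm)
  rowsums <- tapply(td$prop, td$truth, sum)
  expect_equal(as.numeric(rowsums), rep(1, 10), tolerance = 1e-12)
  # a perfect predictor yields a diagonal matrix: emulate by feeding the
  # model its own argmax labels
  pred <- predict(model, ds, type = "class")
  ds_self <- ds
  ds_self$task <- task_ids()[pred + 1L]
  ds_self$class <- encode_class(pred, match(ds_self$group,
                                            impairment_groups()) - 1L)
  cm_self <- predict_confusion(model, ds_self)
  expect_equal(sum(diag(cm_self)), sum(cm_self))
})
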