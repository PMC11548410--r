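# Spectral loss, minibatch features, generator contracts, lowpass filter.
# (Reference oracles live in helper-oracles.R.)

test_that("spectral loss is zero on identical batches and shift-blind", {
  set.seed(7)
  x <- array(rnorm(3 * 300 * 9), c(3, 300, 9))
  expect_equal(spectral_loss(x, x), 0)
  # circular shift preserves the magnitude spectrum
  a <- array(c(1, rep(0, 7)), c(1, 8, 1))
  b <- array(c(0, 1, rep(0, 6)), c(1, 8, 1))
  expect_equal(spectral_loss(a, b), 0, tolerance = 1e-12)
})

test_that("spectral loss matches a naive DFT-by-summation oracle", {
  set.seed(8)
  for (rep in 1:3) {
    xr <- array(rnorm(2 * 20 * 3), c(2, 20, 3))
    xf <- array(rnorm(2 * 20 * 3), c(2, 20, 3))
    expect_equal(spectral_loss(xr, xf), naive_spectral_loss(xr, xf),
                 tolerance = 1e-10)
  }
})

test_that("spectral loss is symmetric, nonnegative, and reorder-invariant", {
  set.seed(9)
  xr <- array(rnorm(4 * 30 * 2), c(4, 30, 2))
  xf <- array(rnorm(4 * 30 * 2), c(4, 30, 2))
  expect_gte(spectral_loss(xr, xf), 0)
  expect_equal(spectral_loss(xr, xf), spectral_loss(xf, xr))
  perm <- c(3, 1, 4, 2)
  expect_equal(spectral_loss(xr, xf),
               spectral_loss(xr[perm, , , drop = FALSE], xf))
  expect_error(spectral_loss(xr, xf[1:2, , , drop = FALSE]),
               class = "reachsynth_invalid_input")
})

test_that("spectral gradient matches finite differences", {
  ns <- asNamespace("reachsynth")
  set.seed(10)
  xr <- array(rnorm(2 * 12 * 2), c(2, 12, 2))
  xf <- array(rnorm(2 * 12 * 2), c(2, 12, 2))
  for (mode in c("batch_mean", "paired")) {
    gr <- ns$spectral_loss_grad(xr, xf, mode)
    eps <- 1e-6
    num <- xf * 0
    for (i in seq_along(xf)) {
      xp <- xf; xp[i] <- xp[i] + eps
      xm <- xf; xm[i] <- xm[i] - eps
      num[i] <- (spectral_loss(xr, xp, mode) -
                   spectral_loss(xr, xm, mode)) / (2 * eps)
    }
    expect_lt(max(abs(num - gr$dx)), 1e-6)
  }
})

test_that("minibatch features follow the exclusion convention and oracle", {
  set.seed(11)
  proj <- array(rnorm(4 * 3 * 2), c(4, 3, 2))
  # single sample: empty sum over j != i
  f1 <- matrix(rnorm(4), 1, 4)
  expect_equal(minibatch_features(f1, proj), matrix(0, 1, 3))
  # two identical rows: distance 0 -> exp(0) = 1 per kernel
  f2 <- matrix(rep(rnorm(4), each = 2), 2, 4)
  expect_equal(minibatch_features(f2, proj), matrix(1, 2, 3),
               tolerance = 1e-12)
  # triple-loop reference on a random instance
  f3 <- matrix(rnorm(3 * 4), 3, 4)
  expect_equal(minibatch_features(f3, proj),
               naive_minibatch_features(f3, proj), tolerance = 1e-10)
  # collapsed batch is distinguishable from a diverse one by construction
  collapsed <- minibatch_features(matrix(1, 4, 4), proj)
  diverse <- minibatch_features(matrix(rnorm(16, sd = 3), 4, 4), proj)
  expect_false(isTRUE(all.equal(collapsed, diverse)))
})

test_that("generator forward obeys shape, determinism, and a live label path", {
  ds <- toy_sine_dataset(8, seed = 3)
  b <- suppressWarnings(train_cgan(ds, toy_train_config(epochs = 2, seed = 5),
                                   toy_gen_config()))
  z <- rnorm(16)
  o1 <- generator_forward(b, z, 0L)
  o2 <- generator_forward(b, z, 0L)
  o3 <- generator_forward(b, z, 3L)
  expect_equal(dim(o1), c(300L, 9L))
  expect_true(all(is.finite(o1)))
  expect_identical(o1, o2)
  expect_false(isTRUE(all.equal(o1, o3)))   # label pathway is live
  expect_error(generator_forward(b, rnorm(7), 0L),
               class = "reachsynth_config_error")
})

test_that("train_cgan keeps bookkeeping contracts and sampling inverts standardization", {
  ds <- toy_sine_dataset(8, seed = 4)
  tc <- toy_train_config(epochs = 3, seed = 6)
  expect_warning(b <- train_cgan(ds, tc, toy_gen_config()),
                 "excluded from conditioning")
  expect_equal(nrow(b$history), 3L)
  expect_true(all(is.finite(as.matrix(b$history))))
  expect_setequal(b$trained_classes, c(0L, 3L))

  s1 <- sample_trials(b, class = rep(0L, 5), seed = 9)
  s2 <- sample_trials(b, class = rep(0L, 5), seed = 9)
  expect_equal(nrow(s1), 5L)
  expect_identical(s1$signal, s2$signal)
  expect_true(all(s1$provenance == "synthetic"))
  # de-standardization oracle: re-standardize and compare with raw output
  set.seed(9L)
  z <- matrix(rnorm(5 * 16), 5, 16)
  raw <- generator_forward(b, z[1, ], 0L)
  restd <- sweep(sweep(s1$signal[[1]], 2, b$channel_means), 2,
                 b$channel_sds, "/")
  expect_lt(max(abs(unname(restd) - unname(raw))), 1e-6)
  expect_error(sample_trials(b, class = 7L, seed = 1),
               class = "reachsynth_invalid_input")
})

test_that("2 Hz zero-phase filter meets its passband and stopband contract", {
  t <- (0:299) / 60
  fit_amp <- function(y, f) {
    X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
    sqrt(sum(stats::coef(stats::lm(y ~ X - 1))^2))
  }
  dc <- lowpass_2hz(matrix(2.5, 300, 9))
  expect_lt(max(abs(dc - 2.5)), 1e-9)
  y05 <- lowpass_2hz(matrix(rep(sin(2 * pi * 0.5 * t), 9), 300, 9))
  expect_lt(abs(fit_amp(y05[, 1], 0.5) - 1), 0.02)
  y5 <- lowpass_2hz(matrix(rep(sin(2 * pi * 5 * t), 9), 300, 9))
  expect_lt(max(abs(y5[50:250, 1])), 10^(-20 / 20))   # >= 20 dB down
  # near-idempotence in the passband
  y05b <- lowpass_2hz(y05)
  expect_lt(max(abs(y05b[, 1] - y05[, 1])), 0.01)
  expect_error(lowpass_2hz(matrix(1, 10, 9)),
               class = "reachsynth_invalid_input")
})
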