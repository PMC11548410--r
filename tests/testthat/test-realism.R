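test_that("range of motion matches closed forms and a per-column oracle", {
  const <- matrix(5, 300, 9)
  expect_equal(unname(range_of_motion(const)), rep(0, 9))

  t <- (0:299) / 60
  m <- matrix(0, 300, 9)
  m[, 3] <- 2 * sin(2 * pi * 1 * t)           # amplitude 2 -> ROM 4
  rom <- range_of_motion(m)
  expect_lt(abs(rom[[3]] - 4) / 4, 0.001)

  set.seed(19)
  r <- matrix(rnorm(300 * 9), 300, 9)
  expect_identical(unname(range_of_motion(r)), naive_rom(r))

  # invariances: time reversal and constant per-channel offset
  off <- sweep(r, 2, rnorm(9) * 10, "+")
  expect_equal(unname(range_of_motion(r)),
               unname(range_of_motion(r[300:1, ])))
  expect_equal(unname(range_of_motion(r)), unname(range_of_motion(off)))
})

test_that("rom_ttest reproduces the closed-form Welch statistic", {
  x <- c(3.1, 2.8, 3.6, 2.9, 3.3)
  y <- c(2.1, 2.6, 1.9, 2.8, 2.2)
  expect_equal(rom_ttest(x, y), naive_welch_p(x, y), tolerance = 1e-8)
  # symmetry, degenerate and insufficient-n handling
  expect_equal(rom_ttest(x, y), rom_ttest(y, x))
  expect_equal(rom_ttest(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_warning(p <- rom_ttest(c(1), c(1, 2, 3)), "Fewer than 2")
  expect_true(is.na(p))
})

test_that("rom_table covers the 10 x 9 x 3 grid and detects known effects", {
  real <- simulate_dataset(4, seed = 51)
  copy <- real
  copy$provenance <- "synthetic"
  rt <- rom_table(real, copy)
  expect_equal(nrow(rt), 270L)
  expect_true(all(rt$p_value[!rt$insufficient] == 1))

  # synthetic with shifted arm gains: arm channels should show smaller p
  shifted <- sim_params(arm_gain = c(control = 0.6, mild = 0.45,
                                     modsev = 0.3))
  synth <- simulate_dataset(4, params = shifted, seed = 52,
                            provenance = "synthetic")
  rt2 <- rom_table(real, synth)
  arm <- rt2$p_value[rt2$channel %in% c("shoulder_x", "shoulder_y",
                                        "shoulder_z", "elbow_x", "elbow_y")]
  trunk <- rt2$p_value[rt2$channel %in% c("T8x", "T8y", "T8z", "T8rz")]
  expect_lt(median(arm, na.rm = TRUE), median(trunk, na.rm = TRUE))
})

test_that("high-band power ratio splits energy at the cutoff correctly", {
  t <- (0:299) / 60
  low <- array(rep(sin(2 * pi * 1 * t), 9), c(1, 300, 9))
  hi <- array(rep(sin(2 * pi * 5 * t), 9), c(1, 300, 9))
  expect_lt(highband_power_ratio(low), 0.01)
  expect_gt(highband_power_ratio(hi), 0.99)
  mix <- array(rep(sin(2 * pi * 1 * t) + sin(2 * pi * 5 * t), 9),
               c(1, 300, 9))
  expect_equal(highband_power_ratio(mix), 0.5, tolerance = 0.02)
  # filtering strictly lowers the ratio whenever high-band power exists
  set.seed(31)
  x <- array(rnorm(2 * 300 * 9), c(2, 300, 9))
  expect_lt(highband_power_ratio(lowpass_2hz(x)), highband_power_ratio(x))
})

test_that("t-SNE embedding is deterministic and separates distinct tasks", {
  ds <- simulate_dataset(6, seed = 61)
  # control-only: the group gains rescale templates, so tasks are "widely
  # separated" within a single impairment level
  sub <- as_trial_dataset(dplyr::filter(tibble::as_tibble(ds),
                                        task %in% c("T03", "T10", "T19"),
                                        group == "control"))
  e1 <- tsne_embed(sub, seed = 5, max_iter = 250)
  e2 <- tsne_embed(sub, seed = 5, max_iter = 250)
  expect_equal(nrow(e1), nrow(sub))
  expect_identical(e1$dim1, e2$dim1)
  sil <- mean_silhouette(cbind(e1$dim1, e1$dim2), e1$task)
  expect_gt(sil, 0)
  expect_error(tsne_embed(as_trial_dataset(head(tibble::as_tibble(ds), 5))),
               class = "reachsynth_invalid_input")
})
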