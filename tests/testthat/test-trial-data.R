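test_that("pad_or_crop crops, pads by repeating the last row, and is idempotent", {
  set.seed(11)
  full <- matrix(rnorm(300 * 9), 300, 9)
  expect_identical(pad_or_crop(full), full)

  short <- matrix(rnorm(250 * 9), 250, 9)
  padded <- pad_or_crop(short)
  expect_equal(dim(padded), c(300L, 9L))
  for (r in 251:300) expect_equal(padded[r, ], short[250, ])

  long <- matrix(rnorm(400 * 9), 400, 9)
  cropped <- pad_or_crop(long)
  # element-wise against a naive slice
  naive <- long[1:300, ]
  expect_identical(cropped, naive)

  expect_identical(pad_or_crop(pad_or_crop(short)), pad_or_crop(short))
  expect_error(pad_or_crop(matrix(numeric(0), 0, 9)),
               class = "reachsynth_invalid_input")
})

test_that("normalize_units converts to cm/rad and round-trips", {
  x <- matrix(1, 4, 9)
  y <- normalize_units(x, "m", "deg")
  expect_equal(y[1, 1], 100)
  expect_equal(y[1, 4], pi / 180)
  x2 <- matrix(180, 4, 9)
  expect_equal(normalize_units(x2, "cm", "deg")[1, 5], pi)

  set.seed(2)
  z <- matrix(rnorm(9 * 9), 9, 9)
  # cm -> m -> cm: scale down by hand, convert back
  zm <- z; zm[, 1:3] <- zm[, 1:3] / 100
  expect_lt(max(abs(normalize_units(zm, "m", "rad") - z)), 1e-12)
  expect_error(normalize_units(z, "furlong", "deg"),
               class = "reachsynth_config_error")
})

test_that("impairment grouping splits at FMMA-UE 42 with 42 in modsev", {
  expect_identical(assign_impairment_group(NA, TRUE), "control")
  expect_identical(assign_impairment_group(55, FALSE), "mild")
  expect_identical(assign_impairment_group(21, FALSE), "modsev")
  expect_identical(assign_impairment_group(42, FALSE), "modsev")
  expect_identical(assign_impairment_group(43, FALSE), "mild")
  expect_error(assign_impairment_group(NA, FALSE),
               class = "reachsynth_invalid_metadata")
  expect_error(assign_impairment_group(70, FALSE),
               class = "reachsynth_invalid_metadata")
})

test_that("severity bands partition 0-66 without gaps or overlaps", {
  expect_identical(severity_band(21), "severe")
  expect_identical(severity_band(42), "moderate")
  expect_identical(severity_band(54), "mild")
  bands <- severity_band(0:66)
  expect_identical(unname(table(bands)[c("severe", "moderate", "mild")]),
                   table(c(rep("s", 25), rep("m", 29), rep("i", 13)))[
                     c("s", "m", "i")] |> unname())
  expect_true(all(bands[0:24 + 1] == "severe"))
  expect_true(all(bands[25:53 + 1] == "moderate"))
  expect_true(all(bands[54:66 + 1] == "mild"))
  expect_error(severity_band(-1), class = "reachsynth_invalid_metadata")
  expect_error(severity_band(67), class = "reachsynth_invalid_metadata")
})

test_that("class encoding is a bijection over the 10 x 3 grid", {
  expect_identical(encode_class(0, 0), 0L)
  expect_identical(encode_class(9, 2), 29L)
  grid <- expand.grid(ti = 0:9, gi = 0:2)
  codes <- encode_class(grid$ti, grid$gi)
  expect_identical(sort(codes), 0:29)
  dec <- decode_class(codes)
  expect_identical(dec$task_index, grid$ti)
  expect_identical(dec$group_index, grid$gi)
  expect_error(encode_class(10, 0), class = "reachsynth_invalid_input")
  expect_error(decode_class(30), class = "reachsynth_invalid_input")
})

test_that("trial dataset validation enforces the 300 x 9 finite contract", {
  ds <- simulate_dataset(1, seed = 5)
  expect_silent(validate_trials(ds))
  bad <- ds
  bad$signal[[3]][10, 2] <- NaN
  expect_error(validate_trials(bad), class = "reachsynth_invalid_input")
  bad2 <- ds
  bad2$signal[[1]] <- bad2$signal[[1]][1:299, ]
  expect_error(validate_trials(bad2), class = "reachsynth_invalid_input")
  counts <- class_counts(ds)
  expect_equal(nrow(counts), 30L)
  expect_true(all(counts$n == 1L))
})
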