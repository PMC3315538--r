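test_that("threshold grids follow the unique/quantile strategies", {
  g <- build_threshold_grid(c(1, 2, 3), strategy = "unique")
  expect_equal(g$thresholds, c(2, 3))

  expect_equal(build_threshold_grid(rep(5, 10), "unique")$thresholds,
               numeric(0))
  expect_equal(build_threshold_grid(rep(5, 10), "quantile")$thresholds,
               numeric(0))

  # nine interior deciles of 1..100, computed with the same quantile rule
  g <- build_threshold_grid(1:100, strategy = "quantile", max_cuts = 9)
  expect_equal(g$thresholds,
               as.numeric(quantile(1:100, probs = (1:9) / 10, names = FALSE)))

  # precision rounding de-duplicates
  g <- build_threshold_grid(c(1, 1.04, 1.06, 2), "unique", precision = 1)
  expect_equal(g$thresholds, c(1.1, 2))
  expect_true(all(diff(g$thresholds) > 0))

  expect_error(build_threshold_grid(character(0)), "non-empty")
  expect_error(build_threshold_grid(letters[1:3]), "non-numeric")
})

test_that("interval_of uses left-closed half-open intervals", {
  expect_identical(interval_of(56, c(40, 60)), 1L)
  expect_identical(interval_of(60, c(40, 60)), 2L)
  expect_identical(interval_of(40, c(40, 60)), 1L)
  expect_identical(interval_of(39.999, c(40, 60)), 0L)
  expect_identical(interval_of(NA, c(40, 60)), NA_integer_)
  expect_identical(interval_of(5, numeric(0)), 0L)

  # monotone non-decreasing in the value for random grids
  set.seed(4)
  for (i in 1:20) {
    th <- sort(runif(sample(1:6, 1), 0, 10))
    v <- sort(runif(50, -2, 12))
    expect_true(all(diff(interval_of(v, th)) >= 0))
  }
})

test_that("encoding one-hots every variable block", {
  d <- data.frame(x = 56)
  enc <- encode_dataset(d, grids = list(x = structure(
    list(thresholds = c(40, 60)), class = "ics_grid")))
  expect_equal(as.numeric(enc$X), c(0, 1, 0))

  d <- data.frame(f = factor("b", levels = c("a", "b", "c")))
  enc <- encode_dataset(d)
  expect_equal(as.numeric(enc$X), c(0, 1, 0))

  d <- data.frame(z = c(0, 1, 1))
  enc <- encode_dataset(d)
  expect_equal(enc$X[, 1], c(1, 0, 0), ignore_attr = TRUE)
  expect_equal(enc$X[, 2], c(0, 1, 1), ignore_attr = TRUE)
})

test_that("encoding partitions, decodes, and flags bad input", {
  set.seed(11)
  d <- data.frame(x = rnorm(60), f = factor(sample(letters[1:3], 60, TRUE)),
                  z = rbinom(60, 1, 0.4))
  enc <- encode_dataset(d, outcomes = rep(c(-1, 1), 30), max_cuts = 5)

  # partition: each variable block sums to exactly one per row
  for (v in unique(enc$group$variable)) {
    cols <- enc$group$column[enc$group$variable == v]
    expect_true(all(rowSums(enc$X[, cols, drop = FALSE]) == 1))
  }

  # decode recovers the interval/level of every value
  dec <- decode_intervals(enc)
  expect_equal(dec[, "x"], interval_of(d$x, enc$grids$x))
  expect_equal(dec[, "f"], as.integer(d$f) - 1L)
  expect_equal(dec[, "z"], d$z)

  # missing values land in the reference interval
  d$x[1] <- NA
  enc2 <- encode_dataset(d, grids = enc$grids)
  expect_equal(unname(enc2$X[1, 1]), 1)

  d_bad <- data.frame(f = "zz")
  expect_error(encode_dataset(d_bad, specs = enc$specs["f"]), "row 1")
  expect_error(
    encode_dataset(data.frame(x = 1), specs = enc$specs, grids = enc$grids),
    "lacks")
  expect_error(encode_dataset(data.frame(x = 1:4), outcomes = c(1, 2, 1, 1)),
               "-1")
})
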