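fixture_weights <- function(w_named, b = 0) {
  # build an ics_weights from named per-variable numeric vectors; continuous
  # blocks get unit-spaced thresholds
  specs <- list(); grids <- list(); group <- NULL; w <- numeric(0); col <- 0L
  for (nm in names(w_named)) {
    wv <- w_named[[nm]]
    K <- length(wv)
    specs[[nm]] <- if (K == 2L) ics_variable(nm, "binary")
                   else ics_variable(nm, "continuous")
    grids[[nm]] <- structure(list(thresholds = if (K == 2L) numeric(0)
                                  else seq_len(K - 1L)), class = "ics_grid")
    group <- rbind(group, data.frame(variable = nm, interval = 0:(K - 1L),
                                     column = col + seq_len(K)))
    w <- c(w, wv); col <- col + K
  }
  structure(list(w = w, b = b, group = group, specs = specs, grids = grids),
            class = "ics_weights")
}

test_that("anchoring zeroes references and preserves predictions", {
  w <- fixture_weights(list(v = c(0.5, 0.5, 1.5)), b = 0)
  a <- anchor_weights(w)
  expect_equal(unname(a$w), c(0, 0, 1.0))
  expect_equal(a$b, 0.5)
  expect_equal(anchor_weights(a), a)              # idempotent

  set.seed(8)
  w2 <- fixture_weights(list(u = rnorm(4), z = rnorm(2)), b = rnorm(1))
  a2 <- anchor_weights(w2)
  X <- matrix(0, 100, 6)
  iu <- sample(4, 100, TRUE); iz <- sample(2, 100, TRUE)
  X[cbind(1:100, iu)] <- 1
  X[cbind(1:100, 4 + iz)] <- 1
  expect_equal(as.numeric(X %*% a2$w) + a2$b,
               as.numeric(X %*% w2$w) + w2$b, tolerance = 1e-12)
})

test_that("normalize-and-round follows the smallest-nonzero rule", {
  w <- fixture_weights(list(A = c(0, 1.5), B = c(0, -7.5, 6.0)))
  ch <- normalize_and_round(w)
  expect_equal(ch$variables$A$points, c(0L, 1L))
  expect_equal(ch$variables$B$points, c(0L, -5L, 4L))

  # exact halves round away from zero: 2.1/0.6 = 3.5 -> 4
  w2 <- fixture_weights(list(A = c(0, 0.6, 2.1)))
  expect_equal(normalize_and_round(w2)$variables$A$points, c(0L, 1L, 4L))

  # all-zero weights give an empty chart
  w3 <- fixture_weights(list(A = c(0, 0, 0)))
  ch3 <- normalize_and_round(w3)
  expect_length(ch3$variables, 0)
  expect_equal(count_intervals(ch3), 0L)

  # adjacent intervals with equal points merge into one row
  w4 <- fixture_weights(list(A = c(0, 1, 1.02, 2)))
  ch4 <- normalize_and_round(w4, zero_tol = 0.1)
  expect_equal(ch4$variables$A$points, c(0L, 1L, 2L))
  expect_length(ch4$variables$A$thresholds, 2L)
})

test_that("chart scoring is additive and handles missing values", {
  fx <- adnexal_fixture()
  base <- fx$patient
  s0 <- score_patient(base, fx$chart)
  # one covariate change moves the score by the point difference
  p2 <- base; p2$acoustic_shadows <- 1
  expect_equal(score_patient(p2, fx$chart) - s0, -5L)
  p3 <- base; p3$age <- 70
  expect_equal(score_patient(p3, fx$chart) - s0, 3L - 1L)
  # missing answers score zero points
  p4 <- base; p4$age <- NA
  expect_equal(score_patient(p4, fx$chart) - s0, -1L)
  # all-baseline patient scores zero
  p0 <- list(age = 20, lesion_diameter = 10, solid_ratio = 0,
             papillations_4plus = 0, papillation_flow = 0,
             irregular_wall = 0, acoustic_shadows = 0, color_score = "1",
             ascites = 0, douglas_fluid = 0)
  expect_equal(score_patient(p0, fx$chart), 0L)
  expect_error(score_patient(c(base[-8], list(color_score = "9")),
                             fx$chart), "unknown level")
})

test_that("integer rounding approximately preserves ranking", {
  co <- generate_cohort(staircase_spec(), n = 800, seed = 21)
  enc <- encode_dataset(co$data, outcomes = co$outcomes,
                        strategy = "quantile", max_cuts = 10)
  w <- icscore:::clean_weights(fit_unweighted(enc, 3))
  ch <- normalize_and_round(w)
  te <- generate_cohort(staircase_spec(), n = 2000, seed = 22)
  f <- predictions <- icscore:::margin_of(
    w, encode_dataset(te$data, specs = enc$specs, grids = enc$grids)$X)
  s <- score_patients(te$data, ch)
  expect_lt(abs(auc(f, te$outcomes) - auc(s, te$outcomes)), 0.02)
})
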