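make_enc <- function(x, y, th = c(3, 7)) {
  encode_dataset(data.frame(x = x),
                 grids = list(x = structure(list(thresholds = th),
                                            class = "ics_grid")),
                 outcomes = y)
}

test_that("objective_value matches its closed forms", {
  set.seed(2)
  enc <- make_enc(runif(25, 0, 10), sample(c(-1, 1), 25, TRUE))
  zero <- icscore:::expand_weights(numeric(2), 0, enc,
                                   icscore:::reduced_structure(enc))
  expect_equal(objective_value(zero, enc, gamma = 1), 25)   # hinge 1 each

  enc1 <- make_enc(runif(12, 0, 10), rep(1, 12))
  one <- icscore:::expand_weights(numeric(2), 1, enc1,
                                  icscore:::reduced_structure(enc1))
  expect_equal(objective_value(one, enc1, gamma = 1), 0)    # margins all 1

  # gauge: shifting a block with intercept compensation leaves it unchanged
  w <- icscore:::expand_weights(c(0.7, -0.4), 0.2, enc,
                                icscore:::reduced_structure(enc))
  w2 <- w; w2$w <- w$w + 5; w2$b <- w$b - 5
  expect_equal(objective_value(w2, enc, 2), objective_value(w, enc, 2))
})

test_that("fit_unweighted solves easy geometry", {
  # all labels +1: separable by the intercept alone, objective 0
  enc <- make_enc(runif(15, 0, 10), rep(1, 15))
  fit <- fit_unweighted(enc, gamma = 0.5)
  expect_lt(attr(fit, "objective"), 1e-7)

  # 1-D sign data with a candidate cut at the true boundary
  set.seed(3)
  x <- runif(40, -1, 1)
  y <- ifelse(x < 0, -1, 1)
  enc <- make_enc(x, y, th = c(-0.5, 0, 0.5))
  fit <- fit_unweighted(enc, gamma = 0.01)
  f <- as.numeric(enc$X %*% fit$w) + fit$b
  expect_true(all(sign(f) == y))                      # zero training error
  expect_equal(attr(fit, "objective"),
               oracle_lp_objective(enc, 0.01), tolerance = 1e-6)

  # overwhelming penalty fuses everything to the majority model
  set.seed(4)
  y2 <- sample(c(-1, 1), 40, TRUE, prob = c(0.7, 0.3))
  enc2 <- make_enc(x, y2)
  fit2 <- fit_unweighted(enc2, gamma = 1e6 * 40)
  expect_true(all(abs(fit2$w) < 1e-4))
  expect_equal(sign(fit2$b), -1)
})

test_that("interior-point objectives match the simplex oracle", {
  for (seed in 1:10) {
    inst <- random_small_instance(seed)
    fit <- fit_unweighted(inst$enc, inst$gamma)
    expect_equal(attr(fit, "objective"),
                 oracle_lp_objective(inst$enc, inst$gamma),
                 tolerance = 1e-6, label = paste("instance", seed))
  }
})

test_that("the simplex backend agrees with the built-in solver", {
  for (seed in c(2, 5, 9)) {
    inst <- random_small_instance(seed)
    a <- fit_unweighted(inst$enc, inst$gamma, solver = "ipm")
    b <- fit_unweighted(inst$enc, inst$gamma, solver = "simplex")
    expect_equal(objective_value(b, inst$enc, inst$gamma),
                 attr(a, "objective"), tolerance = 1e-6)
    expect_equal(attr(b, "objective"),
                 objective_value(b, inst$enc, inst$gamma),
                 tolerance = 1e-8)
  }
})

test_that("reweighting factors follow 1/(|diff| + eps)", {
  enc <- make_enc(c(1, 5, 9), c(-1, 1, 1))
  w <- icscore:::expand_weights(c(0, 0.99), 0, enc,
                                icscore:::reduced_structure(enc))
  st <- compute_reweight_factors(w, eps_c = 0.01)
  expect_equal(st$factors, c(1 / 0.01, 1 / (0.99 + 0.01)))
  expect_true(all(st$factors > 0))

  # enormous eps: factors vanish uniformly, ratios tend to one
  st2 <- compute_reweight_factors(w, eps_c = 1e8)
  expect_true(all(st2$factors < 1e-7))
  expect_equal(st2$factors[1] / st2$factors[2], 1, tolerance = 1e-6)
})

test_that("reweighted fitting honors its contracts", {
  co <- one_var_staircase(150, seed = 7)
  enc <- encode_dataset(co$data, outcomes = co$outcomes,
                        strategy = "quantile", max_cuts = 10)
  gamma <- 2

  # eps so large the weighted problem equals the unweighted one
  uw <- fit_unweighted(enc, gamma)
  rw <- fit_reweighted(enc, gamma, eps_c = 1e6, max_iter = 3)
  expect_equal(objective_value(rw$weights, enc, gamma),
               attr(uw, "objective"), tolerance = 1e-5)

  # convergence flag implies the recorded delta beat the bound
  rw2 <- suppressWarnings(fit_reweighted(enc, gamma, eps_c = 0.1,
                                         tol = 1e-3, max_iter = 20))
  if (rw2$state$converged) expect_lt(rw2$state$last_delta, 1e-3)
  expect_lte(rw2$state$iteration, 20)

  # each inner solve is optimal for its factors: the weighted objective of
  # the new iterate cannot exceed that of the previous iterate
  st <- compute_reweight_factors(uw, 0.1)
  w1 <- icscore:::solve_tv_hinge(enc, gamma, u = st$factors)
  expect_lte(objective_value(w1, enc, gamma, st),
             objective_value(uw, enc, gamma, st) + 1e-6)
})

test_that("interval fusion is monotone along a gamma ladder", {
  co <- one_var_staircase(200, seed = 12)
  enc <- encode_dataset(co$data, outcomes = co$outcomes,
                        strategy = "quantile", max_cuts = 10)
  levels_of <- function(w) {
    ww <- w$w
    ww[abs(ww) < 1e-3] <- 0
    length(unique(round(ww / 1e-3)))
  }
  counts <- sapply(c(0.05, 0.5, 5, 50, 5000), function(g)
    levels_of(fit_unweighted(enc, g)))
  expect_true(all(diff(counts) <= 0))
})
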