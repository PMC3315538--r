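test_that("isotonic link handles separation, flatness and monotonicity", {
  # perfectly separated: step from the lower to the upper clip
  link <- fit_link(1:10, c(rep(0, 5), rep(1, 5)))
  expect_equal(risk_of(3, link), 0.001)
  expect_equal(risk_of(9, link), 0.999)

  # outcome independent of score: flat curve at the prevalence
  set.seed(1)
  s <- sample(0:20, 5000, TRUE)
  y <- rbinom(5000, 1, 0.3)
  link2 <- fit_link(s, y)
  se <- sqrt(0.3 * 0.7 / 5000)
  expect_true(all(abs(link2$knots$risk - mean(y)) < 3 * se + 0.02))

  # monotone contract on arbitrary data
  set.seed(2)
  for (i in 1:5) {
    s <- sample(0:12, 300, TRUE)
    y <- rbinom(300, 1, plogis((s - 6) / 3))
    lk <- fit_link(s, y, method = sample(c("isotonic", "smoothed"), 1))
    expect_true(all(diff(lk$knots$risk) >= -1e-12))
    sc <- sort(sample(-2:15, 6))
    expect_true(all(diff(risk_of(sc, lk)) >= -1e-12))
  }

  expect_error(fit_link(1:5, rep(1, 5)), "both outcome classes")
})

test_that("weighted PAVA matches a dynamic-programming oracle", {
  set.seed(5)
  for (i in 1:10) {
    k <- sample(3:8, 1)
    scores <- sort(sample(0:20, k))
    y <- runif(k)
    w <- sample(1:9, k, TRUE)
    fit <- icscore:::pava(y, w)
    sse_fit <- sum(w * (y - fit)^2)
    sse_dp <- dp_isotonic_sse(y, w)
    expect_lte(sse_fit, sse_dp + 1e-6)      # grid oracle cannot beat PAVA
    expect_true(all(diff(fit) >= -1e-12))
  }
})

test_that("risk_of interpolates, extrapolates flat, and clips", {
  link <- structure(list(method = "isotonic",
                         knots = data.frame(score = c(0, 10),
                                            risk = c(0.2, 0.6)),
                         clip = c(0.001, 0.999)), class = "ics_link")
  expect_equal(risk_of(-5, link), 0.2)       # below the smallest knot
  expect_equal(risk_of(25, link), 0.6)       # above the largest
  expect_equal(risk_of(0, link), 0.2)        # at a knot
  expect_equal(risk_of(5, link), 0.4)        # linear between knots
})

test_that("risk tables merge equal rows and render clip extremes", {
  flat <- fit_link(1:10, c(rep(0, 5), rep(1, 5)))
  rt <- build_risk_table(flat, -2, 14)
  expect_equal(nrow(rt), 2L)                    # one row per clip level
  expect_equal(rt$display, c("<0.001", ">0.99"))
  expect_true(all(rt$score_min[-1] == rt$score_max[-nrow(rt)] + 1))

  same <- structure(list(method = "isotonic",
                         knots = data.frame(score = 0, risk = 0.25),
                         clip = c(0.001, 0.999)), class = "ics_link")
  expect_equal(nrow(build_risk_table(same, 0, 9)), 1L)
})

test_that("the packaged risk table reproduces the printed lookups", {
  fx <- adnexal_fixture()
  expect_equal(risk_lookup(27, fx$risk_table), 0.96)
  expect_equal(risk_lookup(15, fx$risk_table), 0.54)
  expect_equal(nrow(fx$risk_table), 16L)
  expect_true(all(diff(fx$risk_table$risk) >= 0))
})

test_that("smoothed link selects a bandwidth by CV likelihood", {
  set.seed(9)
  s <- sample(0:15, 800, TRUE)
  y <- rbinom(800, 1, plogis((s - 8) / 2.5))
  lk <- fit_link(s, y, method = "smoothed", cv_folds = 5, seed = 3)
  expect_true(all(diff(lk$knots$risk) >= -1e-12))
  # smoothed fit tracks the true curve reasonably
  mid <- risk_of(8, lk)
  expect_lt(abs(mid - 0.5), 0.12)
})
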