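test_that("auc equals the Mann-Whitney concordance probability", {
  expect_equal(auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(2, 8), rep(c(0, 1), 4)), 0.5)

  # enumeration oracle on the worked example
  p <- c(1, 2, 3, 4); y <- c(0, 1, 0, 1)
  pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
  conc <- mean(ifelse(p[pairs$i] > p[pairs$j], 1,
                      ifelse(p[pairs$i] == p[pairs$j], 0.5, 0)))
  expect_equal(auc(p, y), conc)
  expect_equal(auc(p, y), 0.75)

  # invariance under strictly increasing transforms
  set.seed(3)
  pr <- rnorm(200); yy <- rbinom(200, 1, plogis(pr))
  expect_equal(auc(pr, yy), auc(exp(pr), yy))
  expect_equal(auc(pr, yy), auc(rank(pr), yy))

  expect_error(auc(1:5, rep(0, 5)), "both outcome classes")
})

test_that("bootstrap CI is deterministic, brackets the estimate", {
  set.seed(10)
  p <- c(rnorm(60), rnorm(40, 1)); y <- rep(c(0, 1), c(60, 40))
  ci <- auc_ci_bootstrap(p, y, B = 400, seed = 7)
  ci2 <- auc_ci_bootstrap(p, y, B = 400, seed = 7)
  expect_identical(as.numeric(ci), as.numeric(ci2))
  a <- auc(p, y)
  expect_lt(ci[1], a)
  expect_gt(ci[2], a)
  expect_warning(auc_ci_bootstrap(c(1, 1, 2, 2), c(0, 0, 1, 1), B = 50,
                                  seed = 1), "degenerate")
})

test_that("Nagelkerke R2 matches its textbook formula", {
  y <- rep(c(0, 1), c(70, 30))
  expect_equal(r2_adj(rep(0.3, 100), y), 0)

  yy <- rep(c(0, 1), 50)
  expect_gt(r2_adj(ifelse(yy == 1, 0.999, 0.001), yy), 0.98)

  # independent recomputation from the definition
  set.seed(3)
  x <- rnorm(1000)
  y2 <- rbinom(1000, 1, plogis(x))
  p <- plogis(0.9 * x)
  n <- 1000
  ll1 <- sum(dbinom(y2, 1, pmin(pmax(p, 1e-6), 1 - 1e-6), log = TRUE))
  ll0 <- sum(dbinom(y2, 1, mean(y2), log = TRUE))
  expected <- (1 - exp(-2 * (ll1 - ll0) / n)) / (1 - exp(2 * ll0 / n))
  expect_equal(r2_adj(p, y2), expected, tolerance = 1e-10)
})

test_that("calibration groups are equal-count with exact binomial CIs", {
  set.seed(6)
  y <- rbinom(100, 1, 0.4)
  cal <- calibration_groups(rep(mean(y), 100) + runif(100, -1e-9, 1e-9), y)
  expect_equal(cal$ratio, 1, tolerance = 1e-6)
  expect_equal(nrow(cal$groups), 10L)
  expect_true(all(cal$groups$n == 10L))

  # true generating risks: group observations fall inside their CIs
  set.seed(5)
  g <- generate_cohort(staircase_spec(), n = 5000, seed = 5)
  cal2 <- calibration_groups(g$risk, as.integer(g$outcomes == 1))
  inside <- with(cal2$groups, observed >= ci_lower & observed <= ci_upper)
  expect_gte(sum(inside), 8L)
  expect_true(all(cal2$groups$n >= 500))

  expect_error(calibration_groups(runif(50), rep(0, 50)), "prevalence")
})

test_that("cutoff selection maximizes specificity under the floor", {
  scores <- c(10, 12, 14, 5, 8, 11)
  y <- c(1, 1, 1, 0, 0, 0)
  # enumeration oracle
  cand <- 5:15
  sens <- sapply(cand, function(c) mean(scores[y == 1] >= c))
  spec <- sapply(cand, function(c) mean(scores[y == 0] < c))
  ok <- sens >= 0.9
  best <- max(cand[ok][spec[ok] == max(spec[ok])])
  expect_equal(select_cutoff(scores, y, 0.9), best)
  expect_equal(best, 10L)

  # separated classes: the tie rule takes the largest cutoff, sens = spec = 1
  c2 <- select_cutoff(c(10, 12, 1, 2), c(1, 1, 0, 0), 0.9)
  expect_equal(c2, 10L)

  # vacuous floor: pure specificity maximization
  c3 <- select_cutoff(scores, y, 0)
  expect_equal(mean(scores[y == 0] < c3), 1)

  expect_warning(select_cutoff(c(1, 5), c(1, 0), min_sens = 2),
                 "no cutoff")
})

test_that("confusion metrics reproduce the 2x2 arithmetic", {
  s <- c(rep(1, 9), 0, rep(0, 8), 1, 1)
  y <- c(rep(1, 10), rep(0, 10))
  cm <- confusion_at_cutoff(s, y, 1)
  expect_equal(cm$sensitivity, 0.9)
  expect_equal(cm$specificity, 0.8)
  expect_equal(cm$lr_pos, 4.5)
  expect_equal(cm$lr_neg, 0.125)
  expect_equal(cm$dor, 36)
  expect_equal(cm$dor, cm$lr_pos / cm$lr_neg)
  expect_true(cm$dor_ci[1] < 36 && 36 < cm$dor_ci[2])

  # operating point of the published adnexal comparison
  s2 <- c(rep(1, 933), rep(0, 67), rep(1, 143), rep(0, 857))
  y2 <- rep(c(1, 0), c(1000, 1000))
  cm2 <- confusion_at_cutoff(s2, y2, 1)
  expect_equal(cm2$sensitivity, 0.933)
  expect_equal(cm2$specificity, 0.857)
  expect_equal(cm2$lr_pos, 6.53, tolerance = 0.01)
  expect_equal(cm2$lr_neg, 0.078, tolerance = 0.01)
  expect_equal(cm2$dor, 84, tolerance = 0.01)

  # cutoff below every score
  cm3 <- confusion_at_cutoff(s, y, -5)
  expect_equal(cm3$sensitivity, 1)
  expect_equal(cm3$specificity, 0)
})

test_that("the classical score system applies the Sullivan rule", {
  set.seed(14)
  n <- 20000
  d <- data.frame(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(-1 + 0.6 * d$a + 1.8 * d$b))
  ch <- build_classical_score_system(d, y)
  expect_equal(ch$variables$a$points, c(0L, 1L))
  expect_equal(ch$variables$b$points, c(0L, 3L))

  d1 <- data.frame(a = rbinom(n, 1, 0.5))
  y1 <- rbinom(n, 1, plogis(-0.5 + 1.2 * d1$a))
  ch1 <- build_classical_score_system(d1, y1)
  expect_equal(ch1$variables$a$points, c(0L, 1L))
  expect_length(ch1$variables, 1L)
})

test_that("finer user intervals cannot do worse than coarse ones", {
  set.seed(15)
  n <- 4000
  x <- runif(n, 0, 10)
  y <- rbinom(n, 1, plogis(-1.5 + 1.2 * (x >= 3) + 1.2 * (x >= 7)))
  d <- data.frame(x = x)
  fine <- build_classical_score_system(d[1:2000, , drop = FALSE], y[1:2000],
                                       widths = list(x = 1))
  coarse <- build_classical_score_system(d[1:2000, , drop = FALSE], y[1:2000],
                                         widths = list(x = 5))
  te <- 2001:4000
  auc_fine <- auc(score_patients(d[te, , drop = FALSE], fine), y[te])
  auc_coarse <- auc(score_patients(d[te, , drop = FALSE], coarse), y[te])
  expect_gte(auc_fine, auc_coarse)
})
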