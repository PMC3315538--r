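# Shared fixtures and independent oracles.

# Independent LP oracle: boot::simplex on the dual of the hinge+TV program
# (max 1'alpha s.t. A'alpha = G'(mu4 - mu3), 0 <= alpha <= 1,
#  mu3, mu4 >= 0, mu3 + mu4 <= gamma*u), whose optimum equals the primal
# optimum by strong duality.  The dual has a feasible origin, which the
# simplex code requires.
oracle_lp_objective <- function(enc, gamma, u = NULL) {
  struct <- icscore:::reduced_structure(enc)
  A <- cbind(enc$X[, struct$red_cols, drop = FALSE], 1) * enc$y
  G <- struct$G
  n <- nrow(A); d1 <- ncol(A); m <- nrow(G)
  if (is.null(u)) u <- rep(1, m)
  gu <- gamma * u
  Gf <- if (m) cbind(G, 0) else matrix(0, 0, d1)
  a <- c(rep(1, n), rep(0, 2 * m))
  eq <- cbind(t(A), if (m) -t(Gf) else NULL, if (m) t(Gf) else NULL)
  A1 <- rbind(eq, -eq,
              cbind(diag(n), matrix(0, n, 2 * m)),
              if (m) cbind(matrix(0, m, n), diag(m), diag(m)))
  b1 <- c(rep(0, 2 * d1), rep(1, n), gu)
  s <- boot::simplex(a = a, A1 = A1, b1 = b1, maxi = TRUE,
                     n.iter = 5000, eps = 1e-12)
  unname(s$value)
}

# Small random hinge+TV instance: one continuous variable with a few cuts,
# optionally a binary variable.
random_small_instance <- function(seed) {
  set.seed(seed)
  n <- sample(8:30, 1)
  x <- runif(n, 0, 10)
  th <- sort(sample(seq(1, 9, by = 0.5), sample(2:4, 1)))
  d <- data.frame(x = x)
  if (runif(1) < 0.4) d$z <- rbinom(n, 1, 0.5)
  y <- ifelse(runif(n) < plogis(x - 5), 1, -1)
  if (length(unique(y)) < 2) y[1:2] <- c(-1, 1)
  grids <- list(x = structure(list(thresholds = th), class = "ics_grid"))
  list(enc = encode_dataset(d, grids = grids, outcomes = y),
       gamma = 10^runif(1, -2, 1))
}

# One-variable staircase cohort (two true breakpoints) used by the
# sparsification checks.
one_var_staircase <- function(n, seed) {
  sp <- sim_spec(list(
    sim_variable("marker", "uniform", par = c(0, 10), breaks = c(3, 7),
                 effects = c(0, 1, 2))), intercept = -1.5)
  generate_cohort(sp, n, seed)
}

# Exhaustive-ish isotonic oracle: dynamic programming over a fine risk grid
# for the weighted monotone least-squares problem.
dp_isotonic_sse <- function(y, w, grid = seq(0, 1, by = 0.005)) {
  n <- length(y); G <- length(grid)
  cost <- outer(y, grid, function(a, b) (a - b)^2) * w
  best <- cost[1, ]
  for (i in 2:max(n, 2)) {
    if (n == 1) break
    best <- cummin(best) + cost[i, ]
  }
  min(best)
}

expect_no_extra_vars <- function(chart, allowed) {
  expect_true(all(names(chart$variables) %in% allowed))
}
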