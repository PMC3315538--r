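# Training problem: over step-function coefficients w (one per
# variable/interval) and intercept b, minimize
#     sum_i max(0, 1 - y_i f(x_i))  +  gamma * sum_k u_k |(D w)_k|
# where f(x) = sum_pj w_pj I(x_p in interval j) + b and D takes adjacent
# differences within each continuous/binary block and (level - reference)
# within categorical blocks.  The objective is invariant to shifting a whole
# block and compensating b, so the reference interval of every block is
# pinned at 0 ("gauge fixing") and the problem is solved over the reduced
# coordinates.  With u fixed this is an exact LP; it is solved by a
# primal-dual interior-point method whose normal equations live in the
# (d+1)-dimensional reduced coefficient space, so cost per iteration is
# O(n d^2) regardless of the number of hinge/TV constraints.

# ---- reduced design and difference structure --------------------------------

reduced_structure <- function(enc) {
  group <- enc$group
  vars <- unique(group$variable)
  red_cols <- integer(0)       # encoding columns kept (interval >= 1)
  G_i <- integer(0); G_j <- integer(0); G_x <- numeric(0)
  diff_var <- character(0)     # variable of each difference row
  row <- 0L
  for (v in vars) {
    sp <- enc$specs[[v]]
    cols <- group$column[group$variable == v]
    K <- length(cols)
    if (K < 2L) next
    rc <- cols[-1L]            # non-reference columns
    base <- length(red_cols)
    red_cols <- c(red_cols, rc)
    chain <- sp$kind %in% c("continuous", "binary")
    for (j in seq_len(K - 1L)) {
      row <- row + 1L
      G_i <- c(G_i, row); G_j <- c(G_j, base + j); G_x <- c(G_x, 1)
      if (chain && j > 1L) {   # w_j - w_{j-1}; first diff is w_1 - 0
        G_i <- c(G_i, row); G_j <- c(G_j, base + j - 1L); G_x <- c(G_x, -1)
      }
      diff_var <- c(diff_var, v)
    }
  }
  d <- length(red_cols)
  G <- matrix(0, row, d)
  if (row > 0L) G[cbind(G_i, G_j)] <- G_x
  list(red_cols = red_cols, G = G, diff_var = diff_var, d = d)
}

# Full-block weight vector (reference entries = 0) from reduced solution
expand_weights <- function(v, b, enc, struct) {
  w <- numeric(nrow(enc$group))
  w[struct$red_cols] <- v
  names(w) <- colnames(enc$X)
  structure(list(w = w, b = b, group = enc$group, specs = enc$specs,
                 grids = enc$grids),
            class = "ics_weights")
}

#' @export
print.ics_weights <- function(x, digits = 4, ...) {
  cat("<ics_weights> intercept =", format(x$b, digits = digits), "\n")
  for (v in unique(x$group$variable)) {
    idx <- x$group$column[x$group$variable == v]
    cat("  ", v, ": ", paste(format(round(x$w[idx], digits)), collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

# Signed penalized differences of a weight object, in G-row order
weight_differences <- function(weights) {
  group <- weights$group
  out <- numeric(0); vars_out <- character(0)
  for (v in unique(group$variable)) {
    sp <- weights$specs[[v]]
    wv <- weights$w[group$column[group$variable == v]]
    K <- length(wv)
    if (K < 2L) next
    dif <- if (sp$kind %in% c("continuous", "binary")) diff(wv)
           else wv[-1L] - wv[1L]
    out <- c(out, dif)
    vars_out <- c(vars_out, rep(v, K - 1L))
  }
  structure(out, variable = vars_out)
}

#' Training objective of an interval weight vector
#'
#' Hinge loss plus the (optionally reweighted) total-variation penalty.
#'
#' @param weights An `ics_weights` object (see [fit_unweighted()]).
#' @param enc An `ics_encoding` with outcomes.
#' @param gamma Positive trade-off constant.
#' @param factors Optional `ics_reweight` state ([compute_reweight_factors()]);
#'   `NULL` means unit factors.
#' @return Non-negative scalar objective value.
#' @export
objective_value <- function(weights, enc, gamma, factors = NULL) {
  stopifnot(gamma > 0)
  f <- as.numeric(enc$X %*% weights$w) + weights$b
  hinge <- sum(pmax(0, 1 - enc$y * f))
  dif <- weight_differences(weights)
  u <- if (is.null(factors)) rep(1, length(dif)) else factors$factors
  if (length(u) != length(dif))
    stop("reweight factors do not match the difference structure",
         call. = FALSE)
  hinge + gamma * sum(u * abs(dif))
}

# ---- interior-point core ----------------------------------------------------

# min sum(xi) + sum(gu*t) + ridge/2 ||v_w||^2   over v (d+1, last = b), xi, t
# s.t. xi >= 0; A v + xi >= 1; t >= +/- G v.     A includes the intercept col.
tv_hinge_ipm <- function(A, G, gu, ridge = 0, tol = 1e-9, maxit = 200L) {
  n <- nrow(A); d1 <- ncol(A); m <- nrow(G)
  # scale the objective so cost coefficients are O(1); the minimizer is
  # unchanged and extreme penalty weights stop straining the linear algebra
  oscale <- max(1, if (m) max(gu) else 0)
  gu <- gu / oscale
  hinge_c <- 1 / oscale
  ridge <- ridge / oscale
  ridge_diag <- c(rep(ridge, d1 - 1L), 0)
  Gv <- function(v) if (m) as.numeric(G %*% v[-d1]) else numeric(0)
  Gt <- function(x) if (m) c(as.numeric(crossprod(G, x)), 0) else numeric(d1)

  v <- numeric(d1); xi <- rep(2, n); tt <- rep(1, m)
  s1 <- xi; s2 <- as.numeric(A %*% v) + xi - 1; s3 <- tt; s4 <- tt
  mu1 <- rep(hinge_c / 2, n); mu2 <- rep(hinge_c / 2, n)
  mu3 <- pmax(gu / 2, 1e-10); mu4 <- mu3
  cs <- 1 + max(hinge_c, if (m) max(gu) else 0)  # cost scale for residuals
  converged <- FALSE; it <- 0L

  for (it in seq_len(maxit)) {
    Av <- as.numeric(A %*% v); Gvv <- Gv(v)
    rp1 <- xi - s1
    rp2 <- Av + xi - 1 - s2
    rp3 <- tt - Gvv - s3
    rp4 <- tt + Gvv - s4
    rd_v <- ridge_diag * v - as.numeric(crossprod(A, mu2)) + Gt(mu3 - mu4)
    rd_xi <- hinge_c - mu1 - mu2
    rd_t <- gu - mu3 - mu4

    pobj <- hinge_c * sum(xi) + sum(gu * tt) + 0.5 * sum(ridge_diag * v^2)
    dobj <- sum(mu2) - 0.5 * sum(ridge_diag * v^2)
    gap <- abs(pobj - dobj) / (1 + abs(pobj))
    rp_inf <- max(abs(rp1), abs(rp2), if (m) abs(rp3) else 0,
                  if (m) abs(rp4) else 0, 0) / 2
    rd_inf <- max(abs(rd_v), abs(rd_xi), if (m) abs(rd_t) else 0) / cs
    crit <- max(gap, rp_inf, rd_inf)
    if (!is.finite(crit)) break            # numerical breakdown: stop here
    if (crit < tol) { converged <- TRUE; break }

    clampD <- function(mu_, s_) pmin(pmax(mu_ / pmax(s_, 1e-14), 1e-14),
                                     1e14)
    dD1 <- clampD(mu1, s1); dD2 <- clampD(mu2, s2)
    dD3 <- if (m) clampD(mu3, s3) else numeric(0)
    dD4 <- if (m) clampD(mu4, s4) else numeric(0)
    w_hinge <- 1 / (1 / dD1 + 1 / dD2)     # harmonic forms stay finite
    w_tv <- if (m) 4 / (1 / dD3 + 1 / dD4) else numeric(0)
    S <- crossprod(A * sqrt(w_hinge))
    if (m) S <- S + rbind(cbind(crossprod(G * sqrt(w_tv)), 0), 0)
    diag(S) <- diag(S) + ridge_diag
    R <- tryCatch(chol(S), error = function(e) {
      diag(S) <- diag(S) + 1e-8 * (1 + mean(diag(S)))
      chol(S)
    })

    solve_dir <- function(rc1, rc2, rc3, rc4) {
      q1 <- (rc1 + mu1 * rp1) / s1; q2 <- (rc2 + mu2 * rp2) / s2
      q3 <- if (m) (rc3 + mu3 * rp3) / s3 else numeric(0)
      q4 <- if (m) (rc4 + mu4 * rp4) / s4 else numeric(0)
      rho_v <- -rd_v - as.numeric(crossprod(A, q2)) + Gt(q3 - q4)
      rho_xi <- -rd_xi - q1 - q2
      rho_t <- if (m) -rd_t - q3 - q4 else numeric(0)
      rhs <- rho_v - as.numeric(crossprod(A, dD2 * rho_xi / (dD1 + dD2)))
      if (m) rhs <- rhs - Gt((dD4 - dD3) * rho_t / (dD3 + dD4))
      dv <- backsolve(R, forwardsolve(t(R), rhs))
      Adv <- as.numeric(A %*% dv); Gdv <- Gv(dv)
      dxi <- (rho_xi - dD2 * Adv) / (dD1 + dD2)
      dt <- if (m) (rho_t - (dD4 - dD3) * Gdv) / (dD3 + dD4) else numeric(0)
      ds1 <- dxi + rp1; ds2 <- Adv + dxi + rp2
      ds3 <- if (m) dt - Gdv + rp3 else numeric(0)
      ds4 <- if (m) dt + Gdv + rp4 else numeric(0)
      dmu1 <- -(rc1 + mu1 * ds1) / s1; dmu2 <- -(rc2 + mu2 * ds2) / s2
      dmu3 <- if (m) -(rc3 + mu3 * ds3) / s3 else numeric(0)
      dmu4 <- if (m) -(rc4 + mu4 * ds4) / s4 else numeric(0)
      list(dv = dv, dxi = dxi, dt = dt,
           ds = list(ds1, ds2, ds3, ds4), dmu = list(dmu1, dmu2, dmu3, dmu4))
    }
    step_len <- function(x, dx) {
      neg <- dx < 0
      if (!any(neg)) 1 else min(1, min(-x[neg] / dx[neg]))
    }

    s_all <- list(s1, s2, s3, s4); mu_all <- list(mu1, mu2, mu3, mu4)
    mu_bar <- (sum(s1 * mu1) + sum(s2 * mu2) + sum(s3 * mu3) +
               sum(s4 * mu4)) / (2 * n + 2 * m)

    aff <- solve_dir(mu1 * s1, mu2 * s2, mu3 * s3, mu4 * s4)
    ap <- min(mapply(step_len, s_all, aff$ds))
    ad <- min(mapply(step_len, mu_all, aff$dmu))
    mu_aff <- (sum((s1 + ap * aff$ds[[1]]) * (mu1 + ad * aff$dmu[[1]])) +
               sum((s2 + ap * aff$ds[[2]]) * (mu2 + ad * aff$dmu[[2]])) +
               sum((s3 + ap * aff$ds[[3]]) * (mu3 + ad * aff$dmu[[3]])) +
               sum((s4 + ap * aff$ds[[4]]) * (mu4 + ad * aff$dmu[[4]]))) /
              (2 * n + 2 * m)
    sigma <- (mu_aff / max(mu_bar, 1e-300))^3
    if (!is.finite(sigma)) sigma <- 0.5
    sigma <- max(min(sigma, 1), 1e-10)

    dir <- solve_dir(mu1 * s1 + aff$ds[[1]] * aff$dmu[[1]] - sigma * mu_bar,
                     mu2 * s2 + aff$ds[[2]] * aff$dmu[[2]] - sigma * mu_bar,
                     if (m) mu3 * s3 + aff$ds[[3]] * aff$dmu[[3]] -
                       sigma * mu_bar else numeric(0),
                     if (m) mu4 * s4 + aff$ds[[4]] * aff$dmu[[4]] -
                       sigma * mu_bar else numeric(0))
    ap <- 0.9995 * min(mapply(step_len, s_all, dir$ds))
    ad <- 0.9995 * min(mapply(step_len, mu_all, dir$dmu))
    if (!is.finite(ap) || !is.finite(ad) ||
        any(!is.finite(dir$dv))) break     # direction unusable: stop here

    v <- v + ap * dir$dv; xi <- xi + ap * dir$dxi
    if (m) tt <- tt + ap * dir$dt
    s1 <- s1 + ap * dir$ds[[1]]; s2 <- s2 + ap * dir$ds[[2]]
    mu1 <- mu1 + ad * dir$dmu[[1]]; mu2 <- mu2 + ad * dir$dmu[[2]]
    if (m) {
      s3 <- s3 + ap * dir$ds[[3]]; s4 <- s4 + ap * dir$ds[[4]]
      mu3 <- mu3 + ad * dir$dmu[[3]]; mu4 <- mu4 + ad * dir$dmu[[4]]
    }
  }
  list(v = v[-d1], b = v[d1],
       objective = oscale * (hinge_c * sum(xi) + sum(gu * tt) +
                             0.5 * sum(ridge_diag * v^2)),
       iterations = it, converged = converged)
}

# Dense tableau-simplex backend (boot::simplex) on the identical LP, for
# small instances.  The hinge slack is decomposed as xi = (1 - eta) + xi2
# with eta in [0, 1] and xi2 >= 0, which turns every constraint into a <=
# row with non-negative right-hand side so that the origin is feasible (the
# form this simplex implementation requires):
#   max sum(eta) - sum(xi2) - gu' t
#   s.t. eta - xi2 <= A v,  eta <= 1,  |G v| <= t
# over (v+, v-, eta, xi2, t) >= 0; the hinge+TV optimum is n - optimum.
tv_hinge_simplex <- function(A, G, gu, ridge = 0) {
  if (!requireNamespace("boot", quietly = TRUE))
    stop("the 'simplex' backend needs the boot package", call. = FALSE)
  if (ridge > 0)
    stop("the simplex backend solves the pure LP (ridge = 0)", call. = FALSE)
  n <- nrow(A); d1 <- ncol(A); m <- nrow(G)
  Gf <- if (m) cbind(G, 0) else matrix(0, 0, d1)
  a <- c(numeric(2 * d1), rep(1, n), rep(-1, n), -gu)
  Z <- function(r, c) matrix(0, r, c)
  A1 <- rbind(
    cbind(-A, A, diag(n), -diag(n), Z(n, m)),         # eta - xi2 - Av <= 0
    cbind(Z(n, 2 * d1), diag(n), Z(n, n), Z(n, m)),   # eta <= 1
    if (m) cbind(Gf, -Gf, Z(m, 2 * n), -diag(m)),     # Gv - t <= 0
    if (m) cbind(-Gf, Gf, Z(m, 2 * n), -diag(m)))     # -Gv - t <= 0
  b1 <- c(rep(0, n), rep(1, n), rep(0, 2 * m))
  s <- boot::simplex(a = a, A1 = A1, b1 = b1, maxi = TRUE,
                     n.iter = 100 * (2 * d1 + 2 * n + m), eps = 1e-10)
  z <- s$soln
  v <- z[seq_len(d1)] - z[d1 + seq_len(d1)]
  list(v = v[-d1], b = v[d1], objective = n - unname(s$value),
       iterations = NA_integer_, converged = s$solved == 1)
}

solve_tv_hinge <- function(enc, gamma, u = NULL, ridge = 0,
                           solver = c("ipm", "simplex"), tol = 1e-9) {
  solver <- match.arg(solver)
  if (is.null(enc$y)) stop("encoding has no outcome labels", call. = FALSE)
  struct <- reduced_structure(enc)
  A <- cbind(enc$X[, struct$red_cols, drop = FALSE], 1) * enc$y
  m <- nrow(struct$G)
  if (is.null(u)) u <- rep(1, m)
  if (length(u) != m) stop("length(u) != number of differences", call. = FALSE)
  gu <- gamma * u
  sol <- if (solver == "ipm") tv_hinge_ipm(A, struct$G, gu, ridge, tol = tol)
         else tv_hinge_simplex(A, struct$G, gu, ridge)
  out <- expand_weights(sol$v, sol$b, enc, struct)
  attr(out, "objective") <- sol$objective
  attr(out, "iterations") <- sol$iterations
  attr(out, "converged") <- sol$converged
  attr(out, "gamma") <- gamma
  out
}

#' Fit the interval model with unit penalty factors
#'
#' Solves the exact LP: hinge loss plus `gamma` times the total variation of
#' each variable's interval coefficients, with every reference interval
#' pinned at weight zero.
#'
#' @param enc An [encode_dataset()] result carrying outcomes.
#' @param gamma Positive trade-off between misclassification and coefficient
#'   fusion; larger values fuse more intervals.
#' @param ridge Optional tiny quadratic penalty on the coefficients for
#'   solution uniqueness (default 0, a pure LP).
#' @param solver `"ipm"` (the built-in interior-point solver, default) or
#'   `"simplex"` (a dense tableau simplex via the boot package; exact
#'   vertex solutions, small problems only).
#' @param tol Solver convergence tolerance (relative duality gap and
#'   residuals).
#' @return An `ics_weights` object; attributes carry the attained objective
#'   and solver diagnostics.
#' @export
fit_unweighted <- function(enc, gamma, ridge = 0, solver = c("ipm", "simplex"),
                           tol = 1e-9) {
  solve_tv_hinge(enc, gamma, u = NULL, ridge = ridge, solver = solver,
                 tol = tol)
}

#' Penalty reweighting factors
#'
#' Each penalized difference gets factor \eqn{u = 1/(|\Delta| + \epsilon_c)}:
#' small differences are penalized harder on the next pass, sharpening
#' fusion, while large (clinically meaningful) jumps are penalized less.
#'
#' @param weights An `ics_weights` object.
#' @param eps_c Positive constant controlling the strength of reweighting;
#'   large values make all factors equal (no reweighting).
#' @return An object of class `ics_reweight` with elements `factors`
#'   (positive, in difference order), `iteration`, `converged`, `last_delta`.
#' @export
compute_reweight_factors <- function(weights, eps_c) {
  stopifnot(eps_c > 0)
  dif <- weight_differences(weights)
  structure(list(factors = 1 / (abs(as.numeric(dif)) + eps_c),
                 variable = attr(dif, "variable"),
                 iteration = 0L, converged = FALSE, last_delta = NA_real_),
            class = "ics_reweight")
}

#' Iteratively reweighted fit
#'
#' Alternates solving the weighted LP and recomputing the factors of
#' [compute_reweight_factors()], starting from the unweighted solution,
#' until the largest coefficient change falls below `tol` or `max_iter`
#' passes are reached (then the returned state flags non-convergence with a
#' warning).
#'
#' @inheritParams fit_unweighted
#' @param eps_c Reweighting constant (default 0.01 for coefficients on the
#'   usual log-odds scale).
#' @param tol Convergence bound on the maximum absolute coefficient change.
#' @param max_iter Maximum reweighting passes.
#' @param solver_tol Tolerance passed to the inner LP solver.
#' @param init Optional `ics_weights` to seed the first factors from
#'   (default: the unweighted solution).  Warm starts from a milder
#'   reweighting level let coefficient jumps concentrate before they are
#'   sharpened, the usual continuation strategy for reweighted-l1 schemes.
#' @return List with `weights` (`ics_weights`) and `state` (`ics_reweight`).
#' @export
fit_reweighted <- function(enc, gamma, eps_c = 0.01, tol = 1e-4,
                           max_iter = 50L, ridge = 0,
                           solver = c("ipm", "simplex"), solver_tol = 1e-9,
                           init = NULL) {
  stopifnot(gamma > 0, eps_c > 0, tol > 0, max_iter >= 1L)
  solver <- match.arg(solver)
  w <- if (is.null(init))
    fit_unweighted(enc, gamma, ridge = ridge, solver = solver,
                   tol = solver_tol)
  else init
  state <- compute_reweight_factors(w, eps_c)
  delta <- Inf
  for (k in seq_len(max_iter)) {
    w_new <- solve_tv_hinge(enc, gamma, u = state$factors, ridge = ridge,
                            solver = solver, tol = solver_tol)
    delta <- max(abs(c(w_new$w - w$w, w_new$b - w$b)))
    w <- w_new
    state <- compute_reweight_factors(w, eps_c)
    state$iteration <- k
    state$last_delta <- delta
    if (delta < tol) { state$converged <- TRUE; break }
  }
  if (!state$converged)
    warning("reweighting did not converge in ", max_iter,
            " iterations (last delta ", signif(delta, 3), ")", call. = FALSE)
  list(weights = w, state = state)
}
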