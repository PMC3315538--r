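# Cross-validated choice of the fusion penalty gamma and of the
# reweighting constant eps_c.

# Stratified fold ids: a pure function of (y, k, seed).  Redraws (with
# seed+1, +2, ...) if some fold misses a class, which can only happen when
# a class has fewer members than folds.
make_folds <- function(y, k, seed) {
  for (attempt in 0:9) {
    set.seed(seed + attempt)
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(sample.int(k), length(idx)))
    }
    ok <- all(vapply(seq_len(k),
                     function(f) length(unique(y[fold == f])) == 2L,
                     logical(1)))
    if (ok) {
      if (attempt > 0L)
        warning("fold draw left a single-class fold; redrew with seed ",
                seed + attempt, call. = FALSE)
      return(fold)
    }
  }
  stop("could not draw folds with both classes present", call. = FALSE)
}

subset_encoding <- function(enc, idx) {
  out <- enc
  out$X <- enc$X[idx, , drop = FALSE]
  out$y <- enc$y[idx]
  out
}

margin_of <- function(weights, X) as.numeric(X %*% weights$w) + weights$b

# Zero out sub-tolerance solver residue so margins cannot rank patients on
# numerically meaningless weight noise.
clean_weights <- function(weights, zero_tol = 1e-3) {
  weights$w[abs(weights$w) <= zero_tol] <- 0
  weights
}

#' Choose gamma by cross-validated AUC
#'
#' Fits the unweighted interval model per fold and per candidate gamma,
#' scores the held-out fold with the rounded chart (the model's actual
#' prediction), and returns the candidate maximizing the mean out-of-fold
#' AUC; exact ties go to the larger gamma (the sparser model).
#'
#' @param enc An [encode_dataset()] result with outcomes.
#' @param gammas Candidate gamma values; default 13 log-spaced values
#'   covering 1e-3 to 1e3 per patient (scaled by n).
#' @param k Number of stratified folds.
#' @param seed Fold seed.
#' @param solver_tol Inner LP tolerance; fold fits only need to rank
#'   candidates, so a looser tolerance than the final fit is used.
#' @return An `ics_selection` with `gamma`, the per-candidate `table`
#'   (mean and per-fold CV AUC) and the fold seed.
#' @export
cv_select_gamma <- function(enc, gammas = NULL, k = 10L, seed = 1L,
                            solver_tol = 1e-7) {
  n <- nrow(enc$X)
  if (is.null(gammas)) gammas <- n * 10^seq(-3, 3, by = 0.5)
  stopifnot(length(gammas) >= 1L, k >= 2L)
  y <- enc$y
  fold <- make_folds(y, k, seed)
  cv <- matrix(NA_real_, length(gammas), k)
  for (f in seq_len(k)) {
    tr <- subset_encoding(enc, fold != f)
    te <- subset_encoding(enc, fold == f)
    te_y <- y[fold == f]
    for (g in seq_along(gammas)) {
      w <- clean_weights(fit_unweighted(tr, gammas[g], tol = solver_tol))
      s <- chart_scores(te, normalize_and_round(w))
      cv[g, f] <- tryCatch(auc(s, te_y), error = function(e) 0.5)
    }
  }
  mean_auc <- rowMeans(cv)
  best <- max(mean_auc)
  chosen <- max(gammas[mean_auc >= best - 1e-12])
  structure(list(gamma = chosen,
                 table = data.frame(gamma = gammas, cv_auc = mean_auc),
                 fold_auc = cv, k = k, seed = seed),
            class = "ics_selection")
}

#' @export
print.ics_selection <- function(x, ...) {
  cat("<ics_selection>")
  if (!is.null(x$gamma)) cat(" gamma =", format(x$gamma, digits = 4))
  if (!is.null(x$eps_c)) cat(" eps_c =", format(x$eps_c, digits = 4))
  cat(" (", x$k, "-fold, seed ", x$seed, ")\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

# Held-out AUC / log-likelihood / Nagelkerke R2 of one fitted weight
# vector: patients are scored with the rounded chart (the deliverable),
# risks via a link fitted on the training fold's scores.
heldout_metrics <- function(w, tr, te, y_te) {
  chart <- normalize_and_round(clean_weights(w))
  s_tr <- chart_scores(tr, chart)
  s_te <- chart_scores(te, chart)
  link <- tryCatch(fit_link(s_tr, as01(tr$y)), error = function(e) NULL)
  risk <- if (is.null(link)) rep(mean(as01(tr$y)), length(s_te))
          else risk_of(s_te, link)
  c(auc = tryCatch(auc(s_te, y_te), error = function(e) 0.5),
    ll = sum(y_te * log(risk) + (1 - y_te) * log(1 - risk)),
    r2 = tryCatch(r2_adj(risk, y_te), error = function(e) NA_real_))
}

# Reweighting path over a descending eps_c ladder, warm-starting each level
# from the previous solution (continuation).  A few inner passes per level
# suffice under warm starts; the cap also bounds the cost of oscillating
# reweight fixed points.
reweight_path <- function(enc, gamma, grid, anneal = TRUE, max_iter = 8L,
                          solver_tol = 1e-7, ...) {
  base <- fit_unweighted(enc, gamma, tol = solver_tol)
  out <- vector("list", length(grid))
  cur <- base
  for (i in seq_along(grid)) {
    rw <- suppressWarnings(
      fit_reweighted(enc, gamma, eps_c = grid[i], max_iter = max_iter,
                     solver_tol = solver_tol,
                     init = if (anneal) cur else NULL, ...))
    out[[i]] <- rw$weights
    if (anneal) cur <- rw$weights
  }
  list(base = base, stages = out)
}

# Integer scores of encoded rows against a chart (via decoded intervals)
chart_scores <- function(enc, chart) {
  if (!length(chart$variables)) return(rep(0L, nrow(enc$X)))
  dec <- decode_intervals(enc)
  total <- rep(0L, nrow(enc$X))
  for (ent in chart$variables) {
    j <- dec[, ent$name]                     # 0-based raw interval index
    if (ent$kind == "continuous") {
      th_full <- enc$grids[[ent$name]]$thresholds
      pts_full <- ent$points[interval_of(c(-Inf, th_full), ent$thresholds) + 1L]
      total <- total + pts_full[j + 1L]
    } else {
      total <- total + ent$points[j + 1L]
    }
  }
  as.integer(total)
}

#' Choose the reweighting constant eps_c
#'
#' Implements the "comparable performance, minimal intervals" rule: among
#' candidate constants whose k-fold CV AUC, likelihood and Nagelkerke R2
#' are within the given slacks of the unweighted model's, the one yielding
#' the fewest chart intervals wins.  If none qualifies, the candidate with
#' the best CV AUC is returned with a warning.
#'
#' Candidates are visited from mildest (largest eps_c) to sharpest and, by
#' default, each level's fit is warm-started from the previous level's
#' solution (continuation): this lets coefficient jumps concentrate on a
#' single boundary before the penalty on small differences is sharpened,
#' which a cold start from the spread-out unweighted solution would
#' otherwise fuse away wholesale.
#'
#' @param enc An [encode_dataset()] result with outcomes.
#' @param gamma The (already selected) fusion penalty.
#' @param grid Candidate eps_c values (order irrelevant; visited
#'   descending).
#' @param k Folds (default 5).
#' @param auc_slack Allowed CV AUC drop.
#' @param lik_slack Allowed relative CV negative-log-likelihood increase.
#' @param r2_slack Allowed CV R2 drop.
#' @param seed Fold seed.
#' @param anneal Warm-start each eps_c level from the previous (milder)
#'   level's solution.
#' @return An `ics_selection` with `eps_c`, the candidate `table`, and
#'   `weights` - the full-data fit at the chosen level.
#' @export
select_eps_c <- function(enc, gamma, grid = c(1, 0.3, 0.1, 0.03, 0.01),
                         k = 5L, auc_slack = 0.01, lik_slack = 0.02,
                         r2_slack = 0.02, seed = 1L, anneal = TRUE) {
  stopifnot(length(grid) >= 1L)
  grid <- sort(unique(grid), decreasing = TRUE)
  fold <- make_folds(enc$y, k, seed)

  full <- reweight_path(enc, gamma, grid, anneal = anneal)
  intervals <- vapply(full$stages, function(w)
    count_intervals(normalize_and_round(clean_weights(w))), integer(1))
  base_int <- count_intervals(normalize_and_round(clean_weights(full$base)))

  met <- array(NA_real_, c(length(grid) + 1L, k, 3L))
  for (f in seq_len(k)) {
    tr <- subset_encoding(enc, fold != f)
    te <- subset_encoding(enc, fold == f)
    y_te <- as01(enc$y[fold == f])
    path <- reweight_path(tr, gamma, grid, anneal = anneal)
    met[1L, f, ] <- heldout_metrics(path$base, tr, te, y_te)
    for (i in seq_along(grid))
      met[i + 1L, f, ] <- heldout_metrics(path$stages[[i]], tr, te, y_te)
  }
  mm <- apply(met, c(1, 3), mean, na.rm = TRUE)
  tab <- data.frame(eps_c = c(Inf, grid),
                    cv_auc = mm[, 1], cv_loglik = mm[, 2], cv_r2 = mm[, 3],
                    intervals = c(base_int, intervals))
  ref <- tab[1L, ]
  cand <- tab[-1L, ]
  ok <- cand$cv_auc >= ref$cv_auc - auc_slack &
        -cand$cv_loglik <= -ref$cv_loglik * (1 + lik_slack) &
        cand$cv_r2 >= ref$cv_r2 - r2_slack
  ok[is.na(ok)] <- FALSE
  if (any(ok)) {
    pick <- which(ok)
    pick <- pick[order(cand$intervals[pick], -cand$cv_auc[pick])][1L]
  } else {
    warning("no eps_c kept performance within the slacks; ",
            "returning the best-AUC candidate", call. = FALSE)
    pick <- which.max(cand$cv_auc)
  }
  structure(list(eps_c = grid[pick], gamma = gamma, table = tab,
                 weights = full$stages[[pick]], k = k, seed = seed),
            class = "ics_selection")
}
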