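# Discrimination, calibration and cutoff metrics, plus the classical
# Sullivan-style score system used as a comparison baseline.

as01 <- function(outcomes) {
  y <- as.numeric(outcomes)
  if (all(y %in% c(-1, 1))) y <- (y + 1) / 2
  if (!all(y %in% c(0, 1))) stop("outcomes must be 0/1 or -1/+1",
                                 call. = FALSE)
  y
}

#' Area under the ROC curve
#'
#' Mann-Whitney concordance probability: the chance a random event patient
#' outranks a random non-event patient, ties counting one half.  Invariant
#' under strictly increasing transforms of the predictions.
#'
#' @param predictions Numeric risk scores or margins.
#' @param outcomes 0/1 (or -1/+1) outcomes; both classes required.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(predictions, outcomes) {
  y <- as01(outcomes)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("both outcome classes are required for the AUC", call. = FALSE)
  r <- rank(predictions)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bias-corrected percentile bootstrap CI for the AUC
#'
#' Resamples patients with replacement, computes the AUC per replicate, and
#' applies the bias-corrected (BC, no acceleration) percentile adjustment:
#' the normal quantile of the fraction of replicates below the point
#' estimate shifts the percentile endpoints.  Replicates that lose one
#' outcome class are redrawn.
#'
#' @inheritParams auc
#' @param B Number of bootstrap replicates.
#' @param level Nominal coverage.
#' @param seed RNG seed.
#' @return Numeric `c(lower, upper)`; the attribute `"replicates"` carries
#'   the bootstrap AUCs.
#' @export
auc_ci_bootstrap <- function(predictions, outcomes, B = 1000L, level = 0.95,
                             seed = 1L) {
  y <- as01(outcomes)
  n <- length(y)
  point <- auc(predictions, y)
  set.seed(seed)
  reps <- numeric(B)
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2L) break
    }
    reps[b] <- auc(predictions[idx], y[idx])
  }
  if (point == 1 && all(reps == 1)) {
    warning("degenerate AUC of 1 with no bootstrap spread", call. = FALSE)
    return(structure(c(1, 1), replicates = reps))
  }
  frac <- (sum(reps < point) + 0.5 * sum(reps == point)) / B
  frac <- min(max(frac, 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(frac)
  a <- (1 - level) / 2
  plo <- stats::pnorm(2 * z0 + stats::qnorm(a))
  phi <- stats::pnorm(2 * z0 + stats::qnorm(1 - a))
  ci <- as.numeric(stats::quantile(reps, c(plo, phi), type = 6))
  structure(ci, replicates = reps)
}

#' Nagelkerke explained variance of risk predictions
#'
#' Likelihood-ratio R-squared of the predicted risks against the null
#' (prevalence) model, rescaled to a maximum of 1 (Nagelkerke's
#' adjustment).  Risks at exactly 0/1 are clipped before the likelihood.
#'
#' @param risks Predicted event probabilities.
#' @param outcomes 0/1 (or -1/+1) outcomes; both classes required.
#' @return R-squared value (0 for prevalence-only predictions, up to 1).
#' @export
r2_adj <- function(risks, outcomes) {
  y <- as01(outcomes)
  if (length(unique(y)) < 2L) stop("both classes required", call. = FALSE)
  n <- length(y)
  p <- pmin(pmax(risks, 1e-6), 1 - 1e-6)
  ll1 <- sum(y * log(p) + (1 - y) * log(1 - p))
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  r2_cs <- 1 - exp(-2 * (ll1 - ll0) / n)
  r2_cs / (1 - exp(2 * ll0 / n))
}

#' Grouped calibration summary
#'
#' Sorts patients by predicted risk and forms contiguous equal-count groups
#' of at least `min_frac` of the data (remainder joins the last group).
#' Reports per-group mean prediction, observed event fraction and exact
#' Clopper-Pearson 95% CI, plus the overall calibration-in-the-large ratio
#' mean(prediction)/prevalence (1 is ideal).
#'
#' @param risks Predicted probabilities.
#' @param outcomes 0/1 (or -1/+1) outcomes.
#' @param min_frac Minimum group fraction of the data.
#' @return List with `groups` (data frame) and `ratio`.
#' @export
calibration_groups <- function(risks, outcomes, min_frac = 0.10) {
  y <- as01(outcomes)
  n <- length(y)
  if (n < 10L) stop("need at least 10 observations", call. = FALSE)
  if (mean(y) == 0) stop("prevalence is zero; ratio undefined", call. = FALSE)
  size <- ceiling(min_frac * n)
  k <- max(1L, n %/% size)
  sizes <- rep(size, k)
  sizes[k] <- sizes[k] + n - k * size
  ord <- order(risks)
  gid <- rep(seq_len(k), times = sizes)
  groups <- do.call(rbind, lapply(seq_len(k), function(g) {
    i <- ord[gid == g]
    x <- sum(y[i]); m <- length(i)
    data.frame(group = g, n = m,
               mean_predicted = mean(risks[i]),
               observed = x / m,
               ci_lower = if (x == 0) 0 else stats::qbeta(0.025, x, m - x + 1),
               ci_upper = if (x == m) 1 else stats::qbeta(0.975, x + 1, m - x))
  }))
  list(groups = groups, ratio = mean(risks) / mean(y))
}

#' Best-specificity cutoff under a sensitivity floor
#'
#' Among integer cutoffs c (predict an event when score >= c) that attain
#' sensitivity at least `min_sens`, returns the one with maximal
#' specificity; ties resolve to the larger cutoff.  If no cutoff reaches
#' the floor, the minimum score is returned with a warning.
#'
#' @param scores Integer scores.
#' @param outcomes 0/1 (or -1/+1) outcomes; both classes required.
#' @param min_sens Required sensitivity.
#' @return Integer cutoff.
#' @export
select_cutoff <- function(scores, outcomes, min_sens = 0.90) {
  y <- as01(outcomes)
  if (length(unique(y)) < 2L) stop("both classes required", call. = FALSE)
  cand <- seq.int(min(scores), max(scores) + 1L)
  sens <- vapply(cand, function(c) mean(scores[y == 1] >= c), numeric(1))
  spec <- vapply(cand, function(c) mean(scores[y == 0] < c), numeric(1))
  ok <- sens >= min_sens
  if (!any(ok)) {
    warning("no cutoff attains sensitivity ", min_sens,
            "; returning the minimum score", call. = FALSE)
    return(as.integer(min(scores)))
  }
  best <- max(spec[ok])
  as.integer(max(cand[ok & spec >= best - 1e-12]))
}

#' Diagnostic metrics of a score cutoff
#'
#' Sensitivity, specificity, likelihood ratios and the diagnostic odds
#' ratio (DOR = LR+/LR-) of the rule "predict an event when score >=
#' cutoff", with a 95% CI for the DOR from the log-odds normal
#' approximation (0.5 continuity correction when any cell is empty).
#'
#' @param scores Integer (or numeric) scores.
#' @param outcomes 0/1 (or -1/+1) outcomes.
#' @param cutoff Decision cutoff.
#' @return List with `cutoff`, `sensitivity`, `specificity`, `lr_pos`,
#'   `lr_neg`, `dor`, `dor_ci` and the 2x2 `table` counts.
#' @export
confusion_at_cutoff <- function(scores, outcomes, cutoff) {
  y <- as01(outcomes)
  if (length(unique(y)) < 2L) stop("both classes required", call. = FALSE)
  pred <- scores >= cutoff
  tp <- sum(pred & y == 1); fn <- sum(!pred & y == 1)
  tn <- sum(!pred & y == 0); fp <- sum(pred & y == 0)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  lrp <- if (spec == 1) Inf else sens / (1 - spec)
  lrn <- if (spec == 0) Inf else (1 - sens) / spec
  dor <- if (is.infinite(lrp) || lrn == 0) Inf else lrp / lrn
  cc <- if (any(c(tp, fn, tn, fp) == 0)) 0.5 else 0
  lo <- log(((tp + cc) * (tn + cc)) / ((fp + cc) * (fn + cc)))
  se <- sqrt(1 / (tp + cc) + 1 / (fn + cc) + 1 / (fp + cc) + 1 / (tn + cc))
  list(cutoff = cutoff, sensitivity = sens, specificity = spec,
       lr_pos = lrp, lr_neg = lrn, dor = dor,
       dor_ci = exp(lo + c(-1, 1) * stats::qnorm(0.975) * se),
       table = c(tp = tp, fn = fn, fp = fp, tn = tn))
}

#' Classical score system from a logistic model
#'
#' The traditional way to turn a regression into a point chart: fit an
#' ordinary logistic model on the raw variables, cut each continuous
#' variable into user-chosen fixed-width intervals, apply the effect at
#' each interval midpoint, and convert effects to points by dividing by the
#' smallest non-zero effect magnitude and rounding.  Interval placement is
#' the user's guess here, not part of the fit - the contrast with the
#' optimizer-chosen intervals is the point of this baseline.
#'
#' @param data Data frame of raw covariates.
#' @param outcomes 0/1 (or -1/+1) outcomes.
#' @param specs Named list of [ics_variable()] (default inferred).
#' @param widths Named numeric vector/list: interval width per continuous
#'   variable.
#' @return An `ics_score_table`.
#' @export
build_classical_score_system <- function(data, outcomes, specs = NULL,
                                         widths = list()) {
  y <- as01(outcomes)
  if (is.null(specs)) specs <- ics_variables(data)
  df <- data.frame(row.names = seq_len(nrow(data)))
  for (nm in names(specs)) {
    df[[nm]] <- switch(specs[[nm]]$kind,
                       continuous = as.numeric(data[[nm]]),
                       categorical = factor(as.character(data[[nm]]),
                                            levels = specs[[nm]]$levels),
                       binary = as.numeric(data[[nm]]))
  }
  df$.y <- y
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  if (!fit$converged || any(fit$fitted.values > 1 - 1e-10) ||
      any(fit$fitted.values < 1e-10))
    stop("logistic fit separated; consider a penalized fit", call. = FALSE)
  beta <- stats::coef(fit)

  entries <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    if (sp$kind == "continuous") {
      vals <- as.numeric(data[[nm]]); vals <- vals[!is.na(vals)]
      w <- widths[[nm]]
      if (is.null(w)) stop("no interval width given for '", nm, "'",
                           call. = FALSE)
      br <- seq(min(vals), max(vals) + w, by = w)
      mids <- (br[-length(br)] + br[-1L]) / 2
      eff <- beta[[nm]] * (mids - mids[1L])
      entries[[nm]] <- list(name = nm, kind = "continuous", unit = sp$unit,
                            thresholds = br[-c(1L, length(br))], effect = eff)
    } else if (sp$kind == "categorical") {
      eff <- c(0, vapply(sp$levels[-1L], function(l) {
        cf <- beta[[paste0(nm, l)]]
        if (is.null(cf) || is.na(cf)) 0 else cf
      }, numeric(1)))
      entries[[nm]] <- list(name = nm, kind = "categorical", unit = sp$unit,
                            levels = sp$levels, effect = eff)
    } else {
      entries[[nm]] <- list(name = nm, kind = "binary", unit = sp$unit,
                            effect = c(0, beta[[nm]]))
    }
  }
  effs <- unlist(lapply(entries, `[[`, "effect"))
  nz <- abs(effs)[abs(effs) > 1e-10]
  m <- if (length(nz)) min(nz) else 1
  keep <- list()
  for (nm in names(entries)) {
    ent <- entries[[nm]]
    pts <- as.integer(round_half_away(ent$effect / m))
    ent$effect <- NULL
    if (all(pts == 0)) next
    if (ent$kind == "continuous") {
      kp <- which(diff(pts) != 0)
      ent$thresholds <- ent$thresholds[kp]
      ent$points <- pts[c(1L, kp + 1L)]
    } else ent$points <- pts
    keep[[nm]] <- ent
  }
  structure(list(variables = keep, variable_order = names(keep),
                 metadata = list(method = "classical-logistic",
                                 widths = widths)),
            class = "ics_score_table")
}
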