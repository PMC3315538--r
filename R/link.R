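# Monotone link from integer score to event risk, and the score->risk
# lookup table derived from it.

# Weighted pool-adjacent-violators: least-squares monotone non-decreasing
# fit to (y, w).  stats::isoreg has no weights, and aggregated score data
# need them, so the classic pooling loop is implemented here.
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 0L) return(numeric(0))
  val <- y[1]; wt <- w[1]; len <- 1L; k <- 1L
  for (i in seq_len(n)[-1L]) {
    k <- k + 1L
    val[k] <- y[i]; wt[k] <- w[i]; len[k] <- 1L
    while (k > 1L && val[k - 1L] > val[k]) {
      val[k - 1L] <- (wt[k - 1L] * val[k - 1L] + wt[k] * val[k]) /
        (wt[k - 1L] + wt[k])
      wt[k - 1L] <- wt[k - 1L] + wt[k]
      len[k - 1L] <- len[k - 1L] + len[k]
      k <- k - 1L
    }
  }
  rep(val[seq_len(k)], times = len[seq_len(k)])
}

#' Fit the monotone score-to-risk link
#'
#' Estimates a non-decreasing risk curve over the observed integer scores.
#' `method = "isotonic"` (default) is the weighted pool-adjacent-violators
#' solution on the per-score event fractions.  `method = "smoothed"` first
#' applies a Gaussian kernel smoother whose bandwidth minimizes the
#' `cv_folds`-fold cross-validated Bernoulli negative log-likelihood, then
#' restores monotonicity with pool-adjacent-violators.  Fitted risks are
#' clipped away from 0 and 1 so extreme chart rows read "<0.001" and
#' ">0.99" rather than certainties.
#'
#' @param scores Integer scores, one per patient.
#' @param outcomes 0/1 outcomes (or -1/+1, converted).
#' @param method `"isotonic"` or `"smoothed"`.
#' @param cv_folds Folds for the bandwidth selection (smoothed method).
#' @param clip Length-2 risk clip bounds.
#' @param bandwidths Candidate bandwidths in score units (smoothed method);
#'   default 0.5 to half the score range.
#' @param seed Fold-assignment seed (smoothed method).
#' @return An object of class `ics_link`: knots (one per distinct score),
#'   clip bounds, method.
#' @export
fit_link <- function(scores, outcomes, method = c("isotonic", "smoothed"),
                     cv_folds = 10L, clip = c(0.001, 0.999),
                     bandwidths = NULL, seed = 1L) {
  method <- match.arg(method)
  y <- as.numeric(outcomes)
  if (all(y %in% c(-1, 1))) y <- (y + 1) / 2
  if (!all(y %in% c(0, 1))) stop("outcomes must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both outcome classes are needed to estimate a link", call. = FALSE)
  if (length(scores) != length(y)) stop("length mismatch", call. = FALSE)
  stopifnot(all(is.finite(scores)))

  agg <- stats::aggregate(y, by = list(score = scores), FUN = mean)
  cnt <- as.numeric(table(factor(scores, levels = agg$score)))
  ord <- order(agg$score)
  s <- agg$score[ord]; p <- agg$x[ord]; w <- cnt[ord]

  if (method == "smoothed") {
    if (is.null(bandwidths)) {
      span <- max(diff(range(s)), 1)
      bandwidths <- unique(pmax(0.5, span * c(.02, .05, .1, .2, .35, .5)))
    }
    nw <- function(h, s_tr, p_tr, w_tr, s_out) {
      K <- exp(-0.5 * (outer(s_out, s_tr, "-") / h)^2)
      num <- K %*% (w_tr * p_tr); den <- K %*% w_tr
      as.numeric(num / pmax(den, 1e-300))
    }
    set.seed(seed)
    fold <- sample(rep_len(seq_len(cv_folds), length(y)))
    nll <- vapply(bandwidths, function(h) {
      tot <- 0
      for (f in seq_len(cv_folds)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2L) next
        a <- stats::aggregate(y[tr], by = list(score = scores[tr]), FUN = mean)
        wtr <- as.numeric(table(factor(scores[tr], levels = a$score)))
        r <- nw(h, a$score, a$x, wtr, scores[!tr])
        r <- pmin(pmax(r, clip[1]), clip[2])
        tot <- tot - sum(y[!tr] * log(r) + (1 - y[!tr]) * log(1 - r))
      }
      tot
    }, numeric(1))
    h <- bandwidths[which.min(nll)]
    p <- nw(h, s, p, w, s)
  }
  risk <- pmin(pmax(pava(p, w), clip[1]), clip[2])
  structure(list(method = method,
                 knots = data.frame(score = s, risk = risk),
                 clip = clip),
            class = "ics_link")
}

#' @export
print.ics_link <- function(x, ...) {
  cat("<ics_link> ", x$method, " link on ", nrow(x$knots),
      " score knots, risks ", format(min(x$knots$risk), digits = 3), "-",
      format(max(x$knots$risk), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Risk at a given score
#'
#' Piecewise-linear interpolation between the link knots, constant beyond
#' the extreme knots, clipped to the link's bounds.
#'
#' @param score Numeric score(s).
#' @param link An `ics_link`.
#' @return Risk(s) in \[0, 1\], non-decreasing in `score`.
#' @export
risk_of <- function(score, link) {
  k <- link$knots
  r <- if (nrow(k) == 1L) rep(k$risk, length(score))
       else stats::approx(k$score, k$risk, xout = score, rule = 2)$y
  pmin(pmax(r, link$clip[1]), link$clip[2])
}

#' Build the score-to-risk lookup table
#'
#' Evaluates the link at every integer score in range, rounds for display,
#' and merges consecutive scores with identical displayed risk into rows;
#' rows at the clip bounds are displayed as strict inequalities.
#'
#' @param link An `ics_link`.
#' @param score_min,score_max Integer attainable score range.
#' @param display_digits Decimals shown (default 2).
#' @return An object of class `ics_risk_table`: data frame with
#'   `score_min`, `score_max`, `risk` (numeric) and `display` columns.
#' @export
build_risk_table <- function(link, score_min, score_max, display_digits = 2L) {
  stopifnot(score_min <= score_max)
  s <- seq.int(score_min, score_max)
  r <- risk_of(s, link)
  disp <- ifelse(r <= link$clip[1], paste0("<", link$clip[1]),
          ifelse(r >= link$clip[2],
                 paste0(">", floor(r * 10^display_digits) / 10^display_digits),
                 formatC(round(r, display_digits),
                         format = "f", digits = display_digits)))
  runs <- rle(disp)
  hi <- cumsum(runs$lengths); lo <- hi - runs$lengths + 1L
  out <- data.frame(score_min = s[lo], score_max = s[hi],
                    risk = round(r[lo], display_digits),
                    display = runs$values, stringsAsFactors = FALSE)
  out$risk[r[lo] <= link$clip[1]] <- link$clip[1]
  out$risk[r[lo] >= link$clip[2]] <- link$clip[2]
  structure(out, class = c("ics_risk_table", "data.frame"))
}

#' Look up the displayed risk for a score
#'
#' @param score Integer score(s); scores beyond the table range take the
#'   extreme rows.
#' @param table An `ics_risk_table`.
#' @return Numeric risk(s) as displayed in the table.
#' @export
risk_lookup <- function(score, table) {
  vapply(score, function(s) {
    i <- which(table$score_min <= s & s <= table$score_max)
    if (!length(i)) i <- if (s < table$score_min[1]) 1L else nrow(table)
    table$risk[i[1L]]
  }, numeric(1))
}

#' @export
print.ics_risk_table <- function(x, ...) {
  cat("<ics_risk_table>\n")
  rng <- ifelse(x$score_min == x$score_max, as.character(x$score_min),
                paste(x$score_min, "to", x$score_max))
  rng[1] <- paste0("<=", x$score_max[1])
  rng[length(rng)] <- paste0(">=", x$score_min[length(rng)])
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-10s %s\n", rng[i], x$display[i]))
  invisible(x)
}
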