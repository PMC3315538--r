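#' Fit an interval coded score model
#'
#' Learns an additive classifier whose per-variable effects are step
#' functions over automatically selected intervals, then converts it into
#' an integer point chart with a monotone score-to-risk link.  Training
#' minimizes a hinge loss plus a total-variation penalty on adjacent
#' interval coefficients (an exact linear program); an optional iteratively
#' reweighted pass sharpens interval fusion; coefficients are normalized so
#' the smallest retained effect is one point and rounded.
#'
#' @param formula Model formula, `outcome ~ covariates`.  The outcome must
#'   be binary (0/1, logical, -1/+1 or a two-level factor with the second
#'   level the event).
#' @param data Data frame holding the variables.
#' @param gamma Fusion penalty; `NULL` (default) selects it by `cv_folds`-
#'   fold cross-validated AUC over `gamma_grid`.
#' @param gamma_grid Candidate gammas for selection (default 13 log-spaced
#'   values, 1e-3 to 1e3 per patient).
#' @param reweight Run the iteratively reweighted sharpening pass.
#' @param eps_c `"select"` (default) chooses the reweighting constant by
#'   the comparable-performance / minimal-intervals rule over an annealed
#'   candidate ladder ([select_eps_c()]); a number fixes it directly.
#' @param strategy,max_cuts,precision Candidate threshold grid options per
#'   continuous variable (see [build_threshold_grid()]).
#' @param variables Optional named list of [ics_variable()] overriding the
#'   inferred kinds.
#' @param link_method `"isotonic"` (default) or `"smoothed"` score-to-risk
#'   link (see [fit_link()]).
#' @param cv_folds Folds for gamma selection.
#' @param min_sens Sensitivity floor for the stored decision cutoff.
#' @param ridge Optional tiny quadratic penalty for solution uniqueness.
#' @param solver LP backend, `"ipm"` (default) or `"simplex"`.
#' @param tol,max_iter Reweighting convergence bound and iteration cap.
#' @param seed Seed for fold assignment.
#' @return An object of class `ics`: the fitted chart (`chart`), risk table
#'   (`risk_table`), link, anchored real-valued `weights`, selection audit,
#'   decision `cutoff`, and the encoding metadata needed for prediction.
#' @examples
#' cohort <- generate_cohort(staircase_spec(), n = 400, seed = 1)
#' d <- cohort$data; d$y <- cohort$outcomes
#' fit <- ics(y ~ ., data = d, gamma = 8, max_cuts = 8)
#' predict(fit, d[1:3, ], type = "risk")
#' @export
ics <- function(formula, data, gamma = NULL, gamma_grid = NULL,
                reweight = TRUE, eps_c = "select",
                strategy = c("quantile", "unique"), max_cuts = 20L,
                precision = NULL, variables = NULL,
                link_method = c("isotonic", "smoothed"), cv_folds = 10L,
                min_sens = 0.90, ridge = 0, solver = c("ipm", "simplex"),
                tol = 1e-4, max_iter = 50L, seed = 1L) {
  strategy <- match.arg(strategy)
  link_method <- match.arg(link_method)
  solver <- match.arg(solver)
  cl <- match.call()

  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  yraw <- stats::model.response(mf)
  y <- if (is.factor(yraw)) 2 * (as.integer(yraw) - 1) - 1
       else if (is.logical(yraw)) 2 * yraw - 1
       else { v <- as.numeric(yraw); if (all(v %in% c(0, 1))) 2 * v - 1
              else v }
  if (!all(y %in% c(-1, 1)))
    stop("the outcome must be binary", call. = FALSE)
  covars <- mf[, -1L, drop = FALSE]
  if (!is.null(variables)) covars <- covars[, names(variables), drop = FALSE]

  enc <- encode_dataset(covars, specs = variables, outcomes = y,
                        strategy = strategy, max_cuts = max_cuts,
                        precision = precision)

  selection <- NULL
  if (is.null(gamma)) {
    selection <- cv_select_gamma(enc, gammas = gamma_grid, k = cv_folds,
                                 seed = seed)
    gamma <- selection$gamma
  }

  eps_selection <- NULL
  state <- NULL
  if (reweight) {
    if (identical(eps_c, "select")) {
      # sharpest reweighting whose CV performance stays comparable to the
      # unweighted model, visited as an annealed ladder
      eps_selection <- select_eps_c(enc, gamma, seed = seed)
      eps_c <- eps_selection$eps_c
      weights <- eps_selection$weights
    } else {
      rw <- fit_reweighted(enc, gamma, eps_c = eps_c, tol = tol,
                           max_iter = max_iter, ridge = ridge,
                           solver = solver)
      weights <- rw$weights
      state <- rw$state
    }
  } else {
    eps_c <- NA_real_
    weights <- fit_unweighted(enc, gamma, ridge = ridge, solver = solver)
  }
  weights <- clean_weights(anchor_weights(weights))

  chart <- normalize_and_round(weights, metadata = list(
    gamma = gamma, eps_c = eps_c, reweight = reweight,
    n = nrow(covars), created = "icscore fit"))
  scores <- chart_scores(enc, chart)
  link <- fit_link(scores, as01(y), method = link_method, seed = seed)
  rng <- score_range(chart)
  risk_table <- build_risk_table(link, rng[1], rng[2])
  cutoff <- tryCatch(suppressWarnings(select_cutoff(scores, y, min_sens)),
                     error = function(e) NA_integer_)

  structure(list(call = cl, chart = chart, risk_table = risk_table,
                 link = link, weights = weights, gamma = gamma,
                 eps_c = eps_c, reweight_state = state,
                 selection = selection, eps_selection = eps_selection,
                 cutoff = cutoff, min_sens = min_sens,
                 specs = enc$specs, grids = enc$grids,
                 outcome = all.vars(formula)[1L],
                 train = list(scores = scores, y = as01(y)),
                 n = nrow(covars)),
            class = "ics")
}

#' @export
print.ics <- function(x, ...) {
  cat("Interval coded score model (gamma = ", format(x$gamma, digits = 4),
      if (!is.na(x$eps_c)) paste0(", eps_c = ", format(x$eps_c, digits = 4)),
      ", n = ", x$n, ")\n\n", sep = "")
  print(x$chart)
  cat("\nScore to risk:\n")
  print(x$risk_table)
  if (!is.na(x$cutoff))
    cat("\nDecision cutoff (sens >= ", x$min_sens, "): score >= ",
        x$cutoff, "\n", sep = "")
  invisible(x)
}

#' @export
summary.ics <- function(object, ...) {
  s <- object$train$scores; y <- object$train$y
  risk <- risk_of(s, object$link)
  cal <- calibration_groups(risk, y)
  conf <- if (!is.na(object$cutoff))
    confusion_at_cutoff(s, y, object$cutoff) else NULL
  out <- list(model = object,
              auc = auc(s, y), r2 = r2_adj(risk, y),
              calibration = cal, confusion = conf,
              intervals = count_intervals(object$chart))
  class(out) <- "summary.ics"
  out
}

#' @export
print.summary.ics <- function(x, ...) {
  print(x$model)
  cat("\nTraining discrimination: AUC = ", format(x$auc, digits = 3),
      ", Nagelkerke R2 = ", format(x$r2, digits = 3),
      ", intervals used = ", x$intervals, "\n", sep = "")
  cat("Calibration ratio (mean predicted / prevalence): ",
      format(x$calibration$ratio, digits = 3), "\n", sep = "")
  if (!is.null(x$confusion))
    cat(sprintf(
      "At cutoff %d: sens %.3f, spec %.3f, LR+ %.2f, LR- %.3f, DOR %.0f\n",
      x$confusion$cutoff, x$confusion$sensitivity, x$confusion$specificity,
      x$confusion$lr_pos, x$confusion$lr_neg, x$confusion$dor))
  invisible(x)
}

#' @export
coef.ics <- function(object, ...) {
  c(`(Intercept)` = object$weights$b, object$weights$w)
}

new_data_encoding <- function(object, newdata) {
  encode_dataset(newdata[, names(object$specs), drop = FALSE],
                 specs = object$specs, grids = object$grids)
}

#' Predict from an interval coded score model
#'
#' @param object An `ics` fit.
#' @param newdata Data frame of raw covariates.
#' @param type `"score"` (integer chart score), `"risk"` (via the monotone
#'   link), `"margin"` (the real-valued pre-rounding decision value), or
#'   `"class"` (event indicator from the stored score cutoff).
#' @param ... Unused.
#' @return Numeric (or integer) vector, one value per row.
#' @export
predict.ics <- function(object, newdata,
                        type = c("score", "risk", "margin", "class"), ...) {
  type <- match.arg(type)
  if (type == "margin") {
    enc <- new_data_encoding(object, newdata)
    return(margin_of(object$weights, enc$X))
  }
  s <- score_patients(newdata, object$chart)
  switch(type,
         score = s,
         risk = risk_of(s, object$link),
         class = as.integer(s >= object$cutoff))
}

#' @export
residuals.ics <- function(object, type = c("response", "hinge"), ...) {
  type <- match.arg(type)
  if (type == "response")
    object$train$y - risk_of(object$train$scores, object$link)
  else {  # hinge losses of the integer-score classifier at the cutoff
    f <- object$train$scores - object$cutoff + 0.5
    pmax(0, 1 - (2 * object$train$y - 1) * f)
  }
}

#' Simulate outcomes from the fitted risk curve
#'
#' @param object An `ics` fit.
#' @param nsim Number of simulated outcome vectors.
#' @param seed RNG seed.
#' @param newdata Covariates to simulate for (default: training scores).
#' @param ... Unused.
#' @return Data frame, one column per simulation, 0/1 outcomes.
#' @export
simulate.ics <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  risk <- if (is.null(newdata)) risk_of(object$train$scores, object$link)
          else predict(object, newdata, type = "risk")
  out <- as.data.frame(lapply(seq_len(nsim), function(i)
    stats::rbinom(length(risk), 1L, risk)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.ics <- function(x, color = FALSE, ...) {
  render_bars(x$chart, x$risk_table, color = color, ...)
}
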