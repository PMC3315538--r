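# Conversion of fitted real-valued interval weights into the integer point
# chart a clinician fills out by hand, and patient scoring against a chart.

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Anchor interval weights at their reference intervals
#'
#' Subtracts each variable's reference-interval weight from the whole block
#' and absorbs the subtracted amounts into the intercept, so that every
#' baseline answer is worth exactly 0.  Because each block's indicators sum
#' to one per patient, predictions are unchanged.
#'
#' @param weights An `ics_weights` object.
#' @return An `ics_weights` object with zero reference weights; idempotent.
#' @export
anchor_weights <- function(weights) {
  group <- weights$group
  w <- weights$w; b <- weights$b
  for (v in unique(group$variable)) {
    cols <- group$column[group$variable == v]
    ref <- unname(w[cols[1L]])
    w[cols] <- w[cols] - ref
    b <- b + ref
  }
  out <- weights
  out$w <- w; out$b <- b
  out
}

#' Build the integer score chart from anchored weights
#'
#' Implements the normalize-then-round rule: all weights are divided by the
#' smallest non-zero absolute weight (so the weakest retained effect is
#' worth 1 point) and rounded to the nearest integer, exact halves away
#' from zero.  Adjacent intervals of a continuous variable whose rounded
#' points coincide are merged, so the chart shows the minimal question set.
#'
#' @param weights An `ics_weights` object (anchored with [anchor_weights()]
#'   first if necessary; this function anchors defensively).
#' @param zero_tol Absolute magnitude below which a fitted weight is treated
#'   as exactly zero before the smallest-non-zero normalizer is found.
#'   Weights live on the hinge margin scale, where retained effects are
#'   order 0.1-2; anything below this tolerance is numerical residue of the
#'   solver, and letting it define the normalizer would blow the chart up
#'   into meaningless giant integers.
#' @param metadata Optional named list stored with the chart (e.g. gamma,
#'   eps_c, data hash).
#' @return An object of class `ics_score_table`; empty (no variables with
#'   non-zero points) if all weights vanish.
#' @export
normalize_and_round <- function(weights, zero_tol = 1e-3, metadata = list()) {
  weights <- anchor_weights(weights)
  w <- weights$w
  w[!is.finite(w)] <- 0
  w[abs(w) <= zero_tol] <- 0
  nz <- abs(w)[w != 0]
  entries <- list()
  if (length(nz)) {
    m <- min(nz)
    group <- weights$group
    for (v in unique(group$variable)) {
      sp <- weights$specs[[v]]
      cols <- group$column[group$variable == v]
      pts <- as.integer(round_half_away(w[cols] / m))
      if (all(pts == 0)) next
      ent <- list(name = v, kind = sp$kind, unit = sp$unit)
      if (sp$kind == "continuous") {
        th <- weights$grids[[v]]$thresholds
        keep <- which(diff(pts) != 0)        # merge equal adjacent intervals
        ent$thresholds <- th[keep]
        ent$points <- pts[c(1L, keep + 1L)]
      } else if (sp$kind == "categorical") {
        ent$levels <- sp$levels
        ent$points <- pts
      } else {
        ent$points <- pts
      }
      entries[[v]] <- ent
    }
  }
  structure(list(variables = entries,
                 variable_order = names(entries),
                 metadata = metadata),
            class = "ics_score_table")
}

#' @export
print.ics_score_table <- function(x, ...) {
  if (!length(x$variables)) {
    cat("<ics_score_table> empty (no variables selected)\n")
    return(invisible(x))
  }
  cat("<ics_score_table> ", length(x$variables), " variables\n", sep = "")
  for (ent in x$variables) {
    cat("  ", ent$name, " (", ent$kind, ")\n", sep = "")
    lab <- interval_labels(ent)
    for (j in seq_along(ent$points))
      cat(sprintf("    %-38s %+d\n", lab[j], ent$points[j]))
  }
  invisible(x)
}

# Human-readable labels for every interval of a chart entry, in order.
interval_labels <- function(ent) {
  unit <- if (nzchar(ent$unit)) paste0(" ", ent$unit) else ""
  if (ent$kind == "continuous") {
    th <- ent$thresholds
    if (!length(th)) return(paste0("any value", unit))
    lab <- character(length(th) + 1L)
    lab[1L] <- paste0("less than ", th[1L], unit)
    if (length(th) > 1L)
      for (j in seq_len(length(th) - 1L))
        lab[j + 1L] <- paste0("between ", th[j], " (included) and ",
                              th[j + 1L], unit)
    lab[length(th) + 1L] <- paste0(th[length(th)], unit,
                                   " or more (included)")
    lab
  } else if (ent$kind == "categorical") {
    paste0("equal to ", ent$levels)
  } else {
    c("no", "yes")
  }
}

# 0-based interval index of a raw value within a chart entry
chart_interval_of <- function(value, ent) {
  if (is.null(value) || is.na(value) ||
      (is.character(value) && !nzchar(value))) return(NA_integer_)
  if (ent$kind == "continuous")
    interval_of(as.numeric(value), ent$thresholds)
  else if (ent$kind == "categorical") {
    i <- match(as.character(value), ent$levels)
    if (is.na(i))
      stop("unknown level '", value, "' for variable '", ent$name, "'",
           call. = FALSE)
    i - 1L
  } else {
    v <- if (is.logical(value)) as.integer(value) else as.numeric(value)
    if (!v %in% c(0, 1))
      stop("binary variable '", ent$name, "' takes value ", value,
           call. = FALSE)
    as.integer(v)
  }
}

#' Score a patient against a chart
#'
#' Sums the points of the interval containing each covariate value.
#' Missing values contribute the reference answer: 0 points.
#'
#' @param record Named list or one-row data frame of raw covariate values.
#' @param table An `ics_score_table`.
#' @return Integer total score.
#' @export
score_patient <- function(record, table) {
  total <- 0L
  for (ent in table$variables) {
    val <- record[[ent$name]]
    if (is.null(val)) next
    j <- chart_interval_of(val, ent)
    if (!is.na(j)) total <- total + ent$points[j + 1L]
  }
  as.integer(total)
}

#' Score a dataset against a chart
#'
#' @param data Data frame of raw covariates, one row per patient.
#' @param table An `ics_score_table`.
#' @return Integer vector of total scores.
#' @export
score_patients <- function(data, table) {
  vapply(seq_len(nrow(data)),
         function(i) score_patient(lapply(data, `[`, i), table), integer(1))
}

#' Attainable score range of a chart
#'
#' @param table An `ics_score_table`.
#' @return Integer vector `c(min, max)`: the scores of the all-worst and
#'   all-best answer patterns.
#' @export
score_range <- function(table) {
  if (!length(table$variables)) return(c(0L, 0L))
  lo <- sum(vapply(table$variables, function(e) min(e$points), integer(1)))
  hi <- sum(vapply(table$variables, function(e) max(e$points), integer(1)))
  c(lo, hi)
}

#' Count the intervals a chart uses
#'
#' Counts, across variables with at least one non-zero point, the number of
#' chart intervals including each variable's reference interval; a selected
#' binary variable counts 2, a categorical variable counts its number of
#' levels.  Deselected variables contribute nothing.
#'
#' @param table An `ics_score_table`.
#' @return Non-negative integer.
#' @export
count_intervals <- function(table) {
  if (!length(table$variables)) return(0L)
  sum(vapply(table$variables, function(ent) {
    if (all(ent$points == 0)) return(0L)
    switch(ent$kind,
           continuous = length(ent$thresholds) + 1L,
           categorical = length(ent$levels),
           binary = 2L)
  }, integer(1)))
}
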