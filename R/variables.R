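#' Declare a model covariate
#'
#' A variable specification records how a raw column is interpreted:
#' `continuous` variables are split into half-open intervals at learned
#' thresholds, `categorical` variables get one indicator per level, and
#' `binary` variables are treated as a two-level block (answer no / answer
#' yes).
#'
#' @param name Column name, unique within a model.
#' @param kind One of `"continuous"`, `"categorical"`, `"binary"`.
#' @param levels Ordered character vector of category labels (categorical
#'   only; the first level is the reference).  Binary variables always use
#'   levels `0`/`1`.
#' @param unit Free-text display unit (e.g. `"mm"`, `"years"`).
#' @return An object of class `ics_variable`.
#' @export
ics_variable <- function(name, kind = c("continuous", "categorical", "binary"),
                         levels = NULL, unit = "") {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a single non-empty string", call. = FALSE)
  if (kind == "categorical") {
    if (is.null(levels) || length(levels) < 2L)
      stop("categorical variable '", name, "' needs at least 2 levels",
           call. = FALSE)
    levels <- as.character(levels)
    if (anyDuplicated(levels))
      stop("duplicated levels for variable '", name, "'", call. = FALSE)
  } else if (kind == "binary") {
    levels <- c("0", "1")
  } else {
    levels <- NULL
  }
  structure(list(name = name, kind = kind, levels = levels, unit = unit),
            class = "ics_variable")
}

#' @export
print.ics_variable <- function(x, ...) {
  cat("<ics_variable> ", x$name, " (", x$kind,
      if (!is.null(x$levels)) paste0(": ", paste(x$levels, collapse = ", ")),
      if (nzchar(x$unit)) paste0(" [", x$unit, "]"), ")\n", sep = "")
  invisible(x)
}

#' Infer variable specifications from a data frame
#'
#' Factors and character columns become categorical; logical columns and
#' numeric columns taking only the values 0/1 become binary; everything
#' else numeric becomes continuous.
#'
#' @param data A data frame of covariates (outcome column excluded).
#' @return A named list of [ics_variable()] objects.
#' @export
ics_variables <- function(data) {
  specs <- lapply(names(data), function(nm) {
    col <- data[[nm]]
    if (is.factor(col))
      ics_variable(nm, "categorical", levels = levels(col))
    else if (is.character(col))
      ics_variable(nm, "categorical", levels = sort(unique(col[!is.na(col)])))
    else if (is.logical(col))
      ics_variable(nm, "binary")
    else if (is.numeric(col) && all(col[!is.na(col)] %in% c(0, 1)))
      ics_variable(nm, "binary")
    else if (is.numeric(col))
      ics_variable(nm, "continuous")
    else stop("cannot infer a variable kind for column '", nm, "'",
              call. = FALSE)
  })
  names(specs) <- names(data)
  specs
}

#' Build a candidate threshold grid for a continuous variable
#'
#' Candidate cut points define the half-open intervals
#' \eqn{(-\infty,\theta_1), [\theta_1,\theta_2), \ldots, [\theta_K,\infty)}
#' among which the optimizer fuses and selects.  The grid is deliberately
#' dense: interval selection is the optimizer's job, not the grid's.
#'
#' @param values Numeric observations of the variable (missing values are
#'   dropped before cuts are computed).
#' @param strategy `"quantile"` places `max_cuts` equally spaced empirical
#'   quantiles (type 7), de-duplicated; `"unique"` uses every distinct
#'   observed value except the minimum.
#' @param max_cuts Maximum number of cut points.
#' @param precision Optional number of decimal places; cuts are rounded and
#'   re-de-duplicated, which yields chart-friendly thresholds.
#' @return An object of class `ics_grid`: a list with `thresholds`, a
#'   strictly increasing numeric vector (possibly empty).
#' @export
build_threshold_grid <- function(values, strategy = c("quantile", "unique"),
                                 max_cuts = 20L, precision = NULL) {
  strategy <- match.arg(strategy)
  if (length(values) == 0L)
    stop("'values' must be non-empty", call. = FALSE)
  if (!is.numeric(values))
    stop("non-numeric values supplied for a continuous variable",
         call. = FALSE)
  values <- values[!is.na(values)]
  if (length(values) == 0L)
    stop("'values' contains only missing observations", call. = FALSE)
  max_cuts <- as.integer(max_cuts)
  if (max_cuts < 1L) stop("'max_cuts' must be positive", call. = FALSE)

  th <- if (strategy == "unique") {
    u <- sort(unique(values))
    u <- u[-1L]                       # the minimum starts the first interval
    if (length(u) > max_cuts) {
      idx <- unique(round(seq(1L, length(u), length.out = max_cuts)))
      u[idx]
    } else u
  } else {
    p <- seq_len(max_cuts) / (max_cuts + 1)
    unique(as.numeric(stats::quantile(values, probs = p, names = FALSE)))
  }
  th <- th[th > min(values)]          # a cut at/below the minimum is vacuous
  if (!is.null(precision)) {
    th <- sort(unique(round(th, precision)))
    th <- th[th > min(values)]
  }
  structure(list(thresholds = as.numeric(th)), class = "ics_grid")
}

#' Locate the interval containing a value
#'
#' Intervals are half-open with the lower bound included:
#' index 0 is \eqn{(-\infty,\theta_1)}, index j is
#' \eqn{[\theta_j,\theta_{j+1})}, and index K is \eqn{[\theta_K,\infty)}.
#'
#' @param value Numeric value(s); `NA` returns `NA` (scored as the
#'   reference interval, 0 points, downstream).
#' @param grid An `ics_grid` or a numeric vector of thresholds.
#' @return Integer interval index (0-based), vectorized over `value`.
#' @export
interval_of <- function(value, grid) {
  th <- if (inherits(grid, "ics_grid")) grid$thresholds else as.numeric(grid)
  if (is.unsorted(th, strictly = TRUE))
    stop("grid thresholds must be strictly increasing", call. = FALSE)
  if (length(th) == 0L) return(ifelse(is.na(value), NA_integer_, 0L))
  out <- findInterval(value, th)      # left-closed: th[j] <= value < th[j+1]
  as.integer(out)
}

n_intervals <- function(spec, grid) {
  switch(spec$kind,
         continuous  = length(grid$thresholds) + 1L,
         categorical = length(spec$levels),
         binary      = 2L)
}

interval_index_of_value <- function(value, spec, grid) {
  # 0-based interval index of one raw value; NA -> reference (handled by caller)
  if (is.na(value) || (is.character(value) && !nzchar(value)))
    return(NA_integer_)
  switch(spec$kind,
         continuous = interval_of(as.numeric(value), grid),
         categorical = {
           i <- match(as.character(value), spec$levels)
           if (is.na(i))
             stop("unknown level '", value, "' for variable '", spec$name,
                  "'", call. = FALSE)
           i - 1L
         },
         binary = {
           v <- if (is.logical(value)) as.integer(value) else as.numeric(value)
           if (!v %in% c(0, 1))
             stop("binary variable '", spec$name,
                  "' takes value ", value, ", expected 0/1", call. = FALSE)
           as.integer(v)
         })
}

#' Expand a dataset into interval indicators
#'
#' Every variable becomes a block of 0/1 columns, one per interval (or
#' level), in which each row has exactly one 1: continuous variables are cut
#' by their threshold grid, categorical variables are one-hot over their
#' levels, and binary variables form a two-column block.  Missing values
#' fall into the reference (first) interval.
#'
#' @param data Data frame of raw covariates.
#' @param specs Named list of [ics_variable()] (default inferred).
#' @param grids Named list of [build_threshold_grid()] results for the
#'   continuous variables (default built from `data` with `...` options).
#' @param outcomes Optional vector of class labels in \{-1, +1\} (or 0/1,
#'   converted).
#' @param ... Passed to [build_threshold_grid()] when grids are built here.
#' @return An object of class `ics_encoding`: list with the indicator
#'   matrix `X` (n rows, one column per variable/interval pair), `group`
#'   (data frame mapping columns to variable and 0-based interval index),
#'   `y` labels, plus the `specs` and `grids` used.
#' @export
encode_dataset <- function(data, specs = NULL, grids = NULL, outcomes = NULL,
                           ...) {
  if (is.null(specs)) specs <- ics_variables(data)
  if (anyDuplicated(vapply(specs, `[[`, "", "name")))
    stop("variable names must be unique", call. = FALSE)
  missing_cols <- setdiff(names(specs), names(data))
  if (length(missing_cols))
    stop("data lacks declared variable(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.null(grids)) grids <- list()
  for (nm in names(specs)) {
    if (specs[[nm]]$kind == "continuous" && is.null(grids[[nm]])) {
      col <- data[[nm]]
      if (!is.numeric(col))
        stop("non-numeric values in continuous variable '", nm, "'",
             call. = FALSE)
      grids[[nm]] <- if (all(is.na(col)) ||
                         length(unique(col[!is.na(col)])) < 2L)
        structure(list(thresholds = numeric(0)), class = "ics_grid")
      else build_threshold_grid(col, ...)
    }
  }

  n <- nrow(data)
  blocks <- list()
  group <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    gr <- grids[[nm]]
    K <- n_intervals(sp, gr)
    idx <- vapply(seq_len(n), function(i) {
      j <- tryCatch(interval_index_of_value(data[[nm]][i], sp, gr),
                    error = function(e)
                      stop("row ", i, ": ", conditionMessage(e),
                           call. = FALSE))
      if (is.na(j)) 0L else j
    }, integer(1))
    B <- matrix(0, n, K)
    B[cbind(seq_len(n), idx + 1L)] <- 1
    blocks[[nm]] <- B
    group[[nm]] <- data.frame(variable = nm, interval = seq_len(K) - 1L,
                              stringsAsFactors = FALSE)
  }
  X <- do.call(cbind, blocks)
  group <- do.call(rbind, group)
  rownames(group) <- NULL
  group$column <- seq_len(nrow(group))
  colnames(X) <- paste(group$variable, group$interval, sep = ":")

  y <- NULL
  if (!is.null(outcomes)) {
    y <- as.numeric(outcomes)
    if (all(y %in% c(0, 1))) y <- 2 * y - 1
    if (!all(y %in% c(-1, 1)))
      stop("outcomes must be coded -1/+1 (or 0/1)", call. = FALSE)
    if (length(y) != n)
      stop("length(outcomes) != nrow(data)", call. = FALSE)
  }
  structure(list(X = X, group = group, y = y, specs = specs, grids = grids),
            class = "ics_encoding")
}

#' @export
print.ics_encoding <- function(x, ...) {
  cat("<ics_encoding> ", nrow(x$X), " patients, ",
      length(x$specs), " variables, ", ncol(x$X), " interval indicators\n",
      sep = "")
  invisible(x)
}

#' Recover interval indices from an indicator matrix
#'
#' The inverse of [encode_dataset()] up to interval resolution: for each
#' variable block the position of the single 1 in the row.
#'
#' @param enc An `ics_encoding`.
#' @return Integer matrix, n rows, one column per variable (0-based interval
#'   indices).
#' @export
decode_intervals <- function(enc) {
  vars <- unique(enc$group$variable)
  out <- sapply(vars, function(v) {
    cols <- enc$group$column[enc$group$variable == v]
    max.col(enc$X[, cols, drop = FALSE], ties.method = "first") - 1L
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, vars))
  out
}
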