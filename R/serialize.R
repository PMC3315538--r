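# Model JSON: chart + risk table + link + grids + metadata, full-precision
# numbers, versioned schema.  A written-then-read model reproduces every
# score and risk exactly.

ICS_SCHEMA_VERSION <- "1"

#' Write a fitted model (or bare chart) to JSON
#'
#' @param object An `ics` fit or an `ics_score_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ics_model <- function(object, path) {
  if (inherits(object, "ics_score_table"))
    object <- list(chart = object, risk_table = NULL, link = NULL)
  payload <- list(
    schema_version = ICS_SCHEMA_VERSION,
    chart = list(variables = lapply(unname(object$chart$variables),
                                    function(e) e[!vapply(e, is.null,
                                                          TRUE)]),
                 metadata = object$chart$metadata),
    risk_table = if (!is.null(object$risk_table))
      as.data.frame(object$risk_table),
    link = if (!is.null(object$link))
      list(method = object$link$method, knots = object$link$knots,
           clip = object$link$clip),
    specs = if (!is.null(object$specs))
      lapply(unname(object$specs), function(s) s[!vapply(s, is.null, TRUE)]),
    grids = if (!is.null(object$grids))
      lapply(object$grids, `[[`, "thresholds"),
    cutoff = object$cutoff, gamma = object$gamma, eps_c = object$eps_c,
    outcome = object$outcome)
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a model JSON written by [write_ics_model()]
#'
#' @param path JSON file path.
#' @return A list of class `ics_model_file` with `chart`, `risk_table`,
#'   `link`, `specs`, `grids`, `cutoff`; usable with [score_patients()],
#'   [risk_of()] and [predict_model_file()].
#' @export
read_ics_model <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(as.character(p$schema_version), ICS_SCHEMA_VERSION))
    stop("unsupported model schema version", call. = FALSE)
  num <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))
  chr <- function(x) if (is.null(x)) NULL else as.character(unlist(x))
  scl <- function(x) if (is.null(x)) NULL else unlist(x)[[1L]]

  vars <- lapply(p$chart$variables, function(e) {
    out <- list(name = scl(e$name), kind = scl(e$kind),
                unit = if (is.null(e$unit)) "" else scl(e$unit))
    if (out$kind == "continuous")
      out$thresholds <- if (is.null(e$thresholds)) numeric(0)
                        else num(e$thresholds)
    if (out$kind == "categorical") out$levels <- chr(e$levels)
    out$points <- as.integer(num(e$points))
    out
  })
  names(vars) <- vapply(vars, `[[`, "", "name")
  chart <- structure(list(variables = vars, variable_order = names(vars),
                          metadata = lapply(p$chart$metadata, scl)),
                     class = "ics_score_table")

  risk_table <- NULL
  if (!is.null(p$risk_table)) {
    rt <- p$risk_table
    risk_table <- structure(
      data.frame(score_min = vapply(rt, function(r) as.integer(r$score_min),
                                    integer(1)),
                 score_max = vapply(rt, function(r) as.integer(r$score_max),
                                    integer(1)),
                 risk = vapply(rt, function(r) as.numeric(r$risk),
                               numeric(1)),
                 display = vapply(rt, function(r) as.character(r$display),
                                  character(1)),
                 stringsAsFactors = FALSE),
      class = c("ics_risk_table", "data.frame"))
  }

  link <- NULL
  if (!is.null(p$link)) {
    kn <- p$link$knots
    link <- structure(
      list(method = scl(p$link$method),
           knots = data.frame(
             score = vapply(kn, function(k) as.numeric(k$score), numeric(1)),
             risk = vapply(kn, function(k) as.numeric(k$risk), numeric(1))),
           clip = num(p$link$clip)),
      class = "ics_link")
  }

  specs <- NULL
  if (!is.null(p$specs)) {
    specs <- lapply(p$specs, function(s)
      structure(list(name = scl(s$name), kind = scl(s$kind),
                     levels = chr(s$levels),
                     unit = if (is.null(s$unit)) "" else scl(s$unit)),
                class = "ics_variable"))
    names(specs) <- vapply(specs, `[[`, "", "name")
  }
  grids <- NULL
  if (!is.null(p$grids))
    grids <- lapply(p$grids, function(th)
      structure(list(thresholds = if (is.null(th)) numeric(0) else num(th)),
                class = "ics_grid"))
  structure(list(chart = chart, risk_table = risk_table, link = link,
                 specs = specs, grids = grids,
                 cutoff = scl(p$cutoff), gamma = scl(p$gamma),
                 eps_c = scl(p$eps_c), outcome = scl(p$outcome)),
            class = "ics_model_file")
}

#' Score and risk predictions from a model file
#'
#' @param model An `ics_model_file` from [read_ics_model()].
#' @param data Data frame of raw covariates.
#' @return Data frame with `score` and `risk` columns.
#' @export
predict_model_file <- function(model, data) {
  s <- score_patients(data, model$chart)
  risk <- if (!is.null(model$link)) risk_of(s, model$link)
          else if (!is.null(model$risk_table)) risk_lookup(s, model$risk_table)
          else rep(NA_real_, length(s))
  data.frame(score = s, risk = risk)
}
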