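# Synthetic cohorts with known piecewise-constant additive log-odds, and
# the packaged adnexal-mass score chart with its worked-example patient.

#' Declare a generative covariate
#'
#' @param name Column name.
#' @param dist `"uniform"`, `"normal"`, `"binary"`, `"categorical"`, or
#'   `"derived"` (computed from other columns, for interaction strata).
#' @param par Distribution parameters: `c(min, max)`, `c(mean, sd)`,
#'   event probability, or level probabilities (categorical; must sum to 1).
#' @param levels Category labels (categorical).
#' @param breaks Strictly increasing true breakpoints of the log-odds step
#'   function (continuous/derived).
#' @param effects Log-odds contribution per interval (length
#'   `length(breaks) + 1`), per level (categorical), or of the value 1
#'   (binary).  Default all zero: an irrelevant variable.
#' @param derive Function of the data frame so far returning the column
#'   (dist = "derived" only).
#' @return A `ics_sim_variable` list.
#' @export
sim_variable <- function(name, dist = c("uniform", "normal", "binary",
                                        "categorical", "derived"),
                         par = NULL, levels = NULL, breaks = numeric(0),
                         effects = NULL, derive = NULL) {
  dist <- match.arg(dist)
  if (dist == "categorical") {
    if (is.null(levels) || is.null(par) || length(par) != length(levels))
      stop("categorical needs levels and matching probabilities",
           call. = FALSE)
    if (abs(sum(par) - 1) > 1e-8)
      stop("categorical probabilities must sum to 1", call. = FALSE)
    if (is.null(effects)) effects <- numeric(length(levels))
    if (length(effects) != length(levels))
      stop("one effect per level required", call. = FALSE)
  } else if (dist == "binary") {
    if (is.null(par)) par <- 0.5
    if (is.null(effects)) effects <- 0
    if (length(effects) != 1L) stop("binary takes one effect", call. = FALSE)
  } else {
    if (dist == "derived" && !is.function(derive))
      stop("derived variables need a 'derive' function", call. = FALSE)
    if (length(breaks) && is.unsorted(breaks, strictly = TRUE))
      stop("breaks must be strictly increasing", call. = FALSE)
    if (is.null(effects)) effects <- numeric(length(breaks) + 1L)
    if (length(effects) != length(breaks) + 1L)
      stop("need length(breaks) + 1 effects", call. = FALSE)
  }
  structure(list(name = name, dist = dist, par = par, levels = levels,
                 breaks = breaks, effects = effects, derive = derive),
            class = "ics_sim_variable")
}

#' Declare a synthetic cohort
#'
#' @param variables List of [sim_variable()] declarations.
#' @param intercept Baseline log-odds.
#' @return An `ics_sim_spec`.
#' @export
sim_spec <- function(variables, intercept = 0) {
  nms <- vapply(variables, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicated variable names", call. = FALSE)
  names(variables) <- nms
  structure(list(variables = variables, intercept = intercept),
            class = "ics_sim_spec")
}

#' The default staircase cohort
#'
#' Two informative continuous variables with two true breakpoints each
#' (interval effects of magnitude 1 to 2 on the log-odds), one informative
#' binary variable, and three irrelevant variables (two continuous, one
#' binary).  The intercept sets the event prevalence near 0.3, in the range
#' typical of the gynecological cohorts this emulates.
#'
#' @return An `ics_sim_spec`.
#' @export
staircase_spec <- function() {
  sim_spec(list(
    sim_variable("marker_a", "uniform", par = c(0, 10), breaks = c(3, 7),
                 effects = c(0, 1, 2)),
    sim_variable("marker_b", "normal", par = c(50, 10), breaks = c(45, 60),
                 effects = c(0, -1, -2)),
    sim_variable("exposure", "binary", par = 0.4, effects = 1.0),
    sim_variable("noise_a", "uniform", par = c(0, 1)),
    sim_variable("noise_b", "normal", par = c(0, 1)),
    sim_variable("noise_c", "binary", par = 0.5)
  ), intercept = -1.62)
}

step_effect <- function(x, breaks, effects) {
  effects[findInterval(x, breaks) + 1L]
}

#' Draw a synthetic cohort
#'
#' Covariates follow the spec's distributions; the event risk is
#' `plogis(intercept + sum of step effects)` and outcomes are Bernoulli
#' draws from it.  Identical (spec, n, seed) give bit-identical output.
#'
#' @param spec An [sim_spec()] (default [staircase_spec()]).
#' @param n Number of patients.
#' @param seed RNG seed.
#' @return List with `data` (covariate data frame), `outcomes` (-1/+1),
#'   `risk` (the true generating risks) and `spec`.
#' @export
generate_cohort <- function(spec = staircase_spec(), n, seed = 1L) {
  stopifnot(inherits(spec, "ics_sim_spec"), n >= 1L)
  set.seed(seed)
  data <- data.frame(row.names = seq_len(n))
  lin <- rep(spec$intercept, n)
  for (v in spec$variables) {
    col <- switch(v$dist,
                  uniform = stats::runif(n, v$par[1], v$par[2]),
                  normal = stats::rnorm(n, v$par[1], v$par[2]),
                  binary = stats::rbinom(n, 1L, v$par),
                  categorical = sample(v$levels, n, replace = TRUE,
                                       prob = v$par),
                  derived = v$derive(data))
    data[[v$name]] <- col
    lin <- lin + switch(v$dist,
                        binary = v$effects * col,
                        categorical = v$effects[match(col, v$levels)],
                        step_effect(col, v$breaks, v$effects))
  }
  risk <- stats::plogis(lin)
  y <- ifelse(stats::runif(n) < risk, 1, -1)
  list(data = data, outcomes = y, risk = risk, spec = spec)
}

#' Large-sample discrimination ceiling of a cohort spec
#'
#' AUC of the true generating risks against outcomes drawn from them: the
#' best any fitted model can do on this cohort, up to Monte-Carlo error.
#'
#' @param spec An [sim_spec()].
#' @param n Monte-Carlo sample size.
#' @param seed RNG seed.
#' @return AUC value.
#' @export
bayes_auc <- function(spec = staircase_spec(), n = 50000L, seed = 1L) {
  g <- generate_cohort(spec, n, seed)
  auc(g$risk, g$outcomes)
}

#' The packaged adnexal-mass scoring chart
#'
#' The ten-variable malignancy score chart for adnexal (ovarian) masses,
#' its sixteen-row score-to-risk table, and the worked-example patient: a
#' 56-year-old with a 133 mm lesion, solid/lesion ratio 0.74, more than
#' three papillations with blood flow, an irregular cyst wall, no acoustic
#' shadows, no ascites, color score 3 and 18 mm of free fluid, whose total
#' score is 27 and estimated malignancy risk 0.96.
#'
#' @return List with `chart` (`ics_score_table`), `risk_table`
#'   (`ics_risk_table`), `patient` (named list of raw covariates),
#'   `expected_score` (27) and `expected_risk` (0.96).
#' @export
adnexal_fixture <- function() {
  ent <- function(name, kind, points, thresholds = NULL, levels = NULL,
                  unit = "") {
    out <- list(name = name, kind = kind, unit = unit)
    if (kind == "continuous") out$thresholds <- thresholds
    if (kind == "categorical") out$levels <- levels
    out$points <- as.integer(points)
    out
  }
  vars <- list(
    age = ent("age", "continuous", c(0, 1, 3), thresholds = c(40, 60),
              unit = "years"),
    lesion_diameter = ent("lesion_diameter", "continuous",
                          c(0, 1, 3, 4, 5, 8),
                          thresholds = c(40, 75, 95, 140, 200), unit = "mm"),
    solid_ratio = ent("solid_ratio", "continuous", c(0, 4, 7, 8),
                      thresholds = c(0.25, 0.55, 0.90)),
    papillations_4plus = ent("papillations_4plus", "binary", c(0, 4)),
    papillation_flow = ent("papillation_flow", "binary", c(0, 3)),
    irregular_wall = ent("irregular_wall", "binary", c(0, 3)),
    acoustic_shadows = ent("acoustic_shadows", "binary", c(0, -5)),
    color_score = ent("color_score", "categorical", c(0, 1, 3, 5),
                      levels = c("1", "2", "3", "4")),
    ascites = ent("ascites", "binary", c(0, 4)),
    douglas_fluid = ent("douglas_fluid", "continuous", c(0, 2, 4),
                        thresholds = c(10, 20), unit = "mm")
  )
  chart <- structure(list(variables = vars, variable_order = names(vars),
                          metadata = list(source = "adnexal mass chart")),
                     class = "ics_score_table")
  rt <- data.frame(
    score_min = c(-5L, 2L, 5L, 6L, 10L, 12L, 13L, 14L, 15L, 16L, 18L, 20L,
                  24L, 26L, 28L, 31L),
    score_max = c(1L, 4L, 5L, 9L, 11L, 12L, 13L, 14L, 15L, 17L, 19L, 23L,
                  25L, 27L, 30L, 51L),
    risk = c(0.001, 0.01, 0.04, 0.06, 0.10, 0.12, 0.24, 0.36, 0.54, 0.63,
             0.69, 0.91, 0.93, 0.96, 0.98, 0.999),
    display = c("<0.001", "0.01", "0.04", "0.06", "0.10", "0.12", "0.24",
                "0.36", "0.54", "0.63", "0.69", "0.91", "0.93", "0.96",
                "0.98", ">0.99"),
    stringsAsFactors = FALSE)
  rt <- structure(rt, class = c("ics_risk_table", "data.frame"))
  patient <- list(age = 56, lesion_diameter = 133, solid_ratio = 0.74,
                  papillations_4plus = 1, papillation_flow = 1,
                  irregular_wall = 1, acoustic_shadows = 0,
                  color_score = "3", ascites = 0, douglas_fluid = 18)
  list(chart = chart, risk_table = rt, patient = patient,
       expected_score = 27L, expected_risk = 0.96)
}
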