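# Clinician-facing renderings: a yes/no questionnaire and segmented score
# bars with the score-to-risk strip.

#' Render a chart as a questionnaire
#'
#' One yes/no question per non-reference interval with its points (explicit
#' minus for protective answers), followed by the score-to-risk table.
#' Ordering is deterministic: chart variable order, then interval order.
#'
#' @param table An `ics_score_table`.
#' @param risks An `ics_risk_table` (optional).
#' @param format `"text"`, `"markdown"` or `"html"`.
#' @return Character scalar, the rendered document.
#' @export
render_questionnaire <- function(table, risks = NULL,
                                 format = c("text", "markdown", "html")) {
  format <- match.arg(format)
  if (!length(table$variables)) {
    msg <- "No variables selected: every answer scores 0 points."
    return(if (format == "html") paste0("<p>", msg, "</p>") else msg)
  }
  q <- character(0)
  for (ent in table$variables) {
    lab <- interval_labels(ent)
    for (j in seq_along(ent$points)[-1L]) {       # reference row omitted
      if (ent$points[j] == 0) next
      q <- rbind(q, c(sprintf("Is %s %s?", gsub("_", " ", ent$name), lab[j]),
                      sprintf("%+d", ent$points[j])))
    }
  }
  risk_rows <- NULL
  if (!is.null(risks)) {
    rng <- ifelse(risks$score_min == risks$score_max,
                  as.character(risks$score_min),
                  paste(risks$score_min, "to", risks$score_max))
    rng[1] <- paste0("up to ", risks$score_max[1])
    rng[length(rng)] <- paste0(risks$score_min[length(rng)], " or more")
    risk_rows <- cbind(rng, risks$display)
  }
  if (format == "text") {
    out <- c("Score questionnaire", "===================",
             sprintf("%-60s %6s", q[, 1], q[, 2]))
    if (!is.null(risk_rows))
      out <- c(out, "", "Score -> risk", "-------------",
               sprintf("%-14s %s", risk_rows[, 1], risk_rows[, 2]))
    paste(out, collapse = "\n")
  } else if (format == "markdown") {
    out <- c("# Score questionnaire", "", "| Question | Points |",
             "|---|---|", sprintf("| %s | %s |", q[, 1], q[, 2]))
    if (!is.null(risk_rows))
      out <- c(out, "", "## Score to risk", "", "| Score | Risk |",
               "|---|---|",
               sprintf("| %s | %s |", risk_rows[, 1], risk_rows[, 2]))
    paste(out, collapse = "\n")
  } else {
    esc <- function(x) gsub("<", "&lt;", gsub(">", "&gt;",
                                              gsub("&", "&amp;", x)))
    out <- c("<h1>Score questionnaire</h1>", "<table>",
             "<tr><th>Question</th><th>Points</th></tr>",
             sprintf("<tr><td>%s</td><td>%s</td></tr>",
                     esc(q[, 1]), esc(q[, 2])), "</table>")
    if (!is.null(risk_rows))
      out <- c(out, "<h2>Score to risk</h2>", "<table>",
               "<tr><th>Score</th><th>Risk</th></tr>",
               sprintf("<tr><td>%s</td><td>%s</td></tr>",
                       esc(risk_rows[, 1]), esc(risk_rows[, 2])), "</table>")
    paste(out, collapse = "\n")
  }
}

# Diverging blue-white-red color for points, symmetric about zero so equal
# protective and risk magnitudes get equal saturation.
points_color <- function(points, max_abs) {
  if (max_abs == 0) return(rep("#FFFFFF", length(points)))
  ramp <- grDevices::colorRamp(c("#2166AC", "#FFFFFF", "#B2182B"))
  v <- (points / max_abs + 1) / 2
  grDevices::rgb(ramp(v), maxColorValue = 255)
}

#' Render a chart as segmented score bars
#'
#' One horizontal bar per variable, segmented by interval and labelled with
#' its points; a bottom strip maps the total score to risk.  In color mode
#' points map through a diverging blue (protective) - white (zero) - red
#' (risk) scale, symmetric about zero.
#'
#' @param table An `ics_score_table`.
#' @param risks An `ics_risk_table`.
#' @param color Use the diverging color scale.
#' @param file Optional output path ending in `.png` or `.svg`; `NULL`
#'   draws on the current device.
#' @return Invisibly, the layout data frame (variable, label, points,
#'   segment coordinates, fill color) that was drawn - a deterministic
#'   record of the drawing commands.
#' @export
render_bars <- function(table, risks = NULL, color = FALSE, file = NULL) {
  if (!length(table$variables))
    stop("cannot render an empty chart", call. = FALSE)
  max_abs <- max(abs(unlist(lapply(table$variables, `[[`, "points"))), 1)
  layout <- do.call(rbind, lapply(table$variables, function(ent) {
    k <- length(ent$points)
    data.frame(variable = ent$name, label = interval_labels(ent),
               points = ent$points,
               xleft = (seq_len(k) - 1) / k, xright = seq_len(k) / k,
               fill = if (color) points_color(ent$points, max_abs)
                      else rep("#EEEEEE", k),
               stringsAsFactors = FALSE)
  }))
  rownames(layout) <- NULL

  draw <- function() {
    vars <- unique(layout$variable)
    nv <- length(vars)
    has_risk <- !is.null(risks)
    graphics::par(mar = c(1, 9, 2, 1))
    graphics::plot(0, 0, type = "n", xlim = c(0, 1),
                   ylim = c(-(nv + if (has_risk) 1.8 else 0.5), 0),
                   axes = FALSE, xlab = "", ylab = "",
                   main = "Interval coded score chart")
    for (i in seq_along(vars)) {
      seg <- layout[layout$variable == vars[i], ]
      y0 <- -i; y1 <- -i + 0.7
      graphics::rect(seg$xleft, y0, seg$xright, y1, col = seg$fill,
                     border = "grey30")
      graphics::text((seg$xleft + seg$xright) / 2, (y0 + y1) / 2,
                     sprintf("%+d", seg$points), cex = 0.8)
      graphics::mtext(gsub("_", " ", vars[i]), side = 2, at = (y0 + y1) / 2,
                      las = 1, line = 0.5, cex = 0.8)
    }
    if (has_risk) {
      k <- nrow(risks)
      x0 <- (seq_len(k) - 1) / k; x1 <- seq_len(k) / k
      y0 <- -(nv + 1.5); y1 <- y0 + 0.7
      rc <- if (color) points_color(2 * risks$risk - 1, 1)
            else rep("#DDDDDD", k)
      graphics::rect(x0, y0, x1, y1, col = rc, border = "grey30")
      graphics::text((x0 + x1) / 2, (y0 + y1) / 2, risks$display, cex = 0.6,
                     srt = 45)
      graphics::mtext("score -> risk", side = 2, at = (y0 + y1) / 2,
                      las = 1, line = 0.5, cex = 0.8)
    }
  }
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    ok <- tryCatch({
      switch(ext,
             png = grDevices::png(file, width = 900, height = 600),
             svg = grDevices::svg(file, width = 9, height = 6),
             stop("unsupported figure format '", ext, "'", call. = FALSE))
      TRUE
    }, error = function(e) stop("cannot open figure file: ",
                                conditionMessage(e), call. = FALSE))
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
  } else {
    draw()
  }
  invisible(layout)
}
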