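#' Healthy weight range for a height
#'
#' Converts the healthy BMI range (18.5-25 kg/m^2) into a weight range for
#' the respondent's height. The report shows this range, never the BMI
#' itself.
#'
#' @param height Height in metres (plausible range 0.5-2.5, exclusive).
#' @return Named numeric `c(low = 18.5 * h^2, high = 25 * h^2)` in kg.
#' @export
#' @examples
#' weight_range(1.80)  # 59.94, 81.00
weight_range <- function(height) {
  if (!is.numeric(height) || is.na(height) || height <= 0.5 || height >= 2.5) {
    stop("implausible height (metres expected): ", height, call. = FALSE)
  }
  c(low = 18.5 * height^2, high = 25 * height^2)
}

#' Weight bar with the respondent's position
#'
#' The arrow position is the respondent's weight expressed as a fraction of
#' the healthy (green) zone: 0 at the lower bound, 1 at the upper bound,
#' clamped to the bar ends with an explicit out-of-range flag rather than
#' drawn off-bar.
#'
#' @param height Metres.
#' @param weight Kilograms.
#' @return List with `healthy_low`, `healthy_high`, `current`,
#'   `arrow_position` (clamped to \[0, 1\]) and `out_of_range`
#'   (`"below"`, `"above"` or `NA`).
#' @export
weight_bar <- function(height, weight) {
  wr <- weight_range(height)
  if (!is.numeric(weight) || is.na(weight) || weight <= 0) {
    stop("weight must be > 0", call. = FALSE)
  }
  pos <- (weight - wr[["low"]]) / (wr[["high"]] - wr[["low"]])
  out <- if (pos < 0) "below" else if (pos > 1) "above" else NA_character_
  list(healthy_low = wr[["low"]], healthy_high = wr[["high"]],
       current = weight,
       arrow_position = min(max(pos, 0), 1),
       out_of_range = out)
}

#' Build the full personalised nutrition report
#'
#' Runs the whole pipeline: daily intakes, m-AHEI scoring, target selection,
#' message composition, healthy weight range and (optionally) the Baecke
#' activity block, assembled into a single report document. The advice
#' messages come first, followed by the Healthy Eating Score, the 11
#' component bars in two labelled groups, and the weight/activity bars.
#'
#' @param response An [ffq_response()].
#' @param foods A [load_food_table()] table.
#' @param specs A [load_mahei_specs()] spec set.
#' @param templates A [load_templates()] template set.
#' @param freqs Frequency dialect (defaults to the packaged one).
#' @param timestamp Report timestamp string; defaults to the current UTC
#'   time. Injected so that reproducible pipelines can fix it.
#' @return An object of class `enutri_report`.
#' @export
build_report <- function(response, foods, specs, templates,
                         freqs = load_frequencies(),
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                            tz = "UTC")) {
  profile <- daily_intake(response, foods, freqs)
  sex <- response$respondent$sex
  score <- healthy_eating_score(profile, specs, sex)
  msgs <- compose_report_messages(profile, score, templates,
                                  response$respondent$name)
  activity <- NULL
  if (!is.null(response$activity)) {
    res <- baecke_indices(response$activity)
    activity <- c(res, list(band = activity_band(res)))
  }
  structure(
    list(intro = msgs$intro,
         messages = msgs$messages,
         healthy_eating = score,
         group_subheadings = c(
           recommended = "Recommended Foods (The higher the better)",
           limit = "Foods to Limit (The lower the better)"),
         weight_bar = weight_bar(response$respondent$height,
                                 response$respondent$weight),
         activity = activity,
         config_version = specs$version,
         timestamp = timestamp),
    class = "enutri_report"
  )
}

report_to_list <- function(report) {
  sc <- report$healthy_eating
  comps <- sc$components
  comps$displayed_pct_rounded <- round_half_up(comps$displayed_pct)
  list(
    intro = report$intro,
    messages = lapply(report$messages, function(m) {
      list(component = m$component,
           direction = m$direction,
           displayed_pct = m$displayed_pct,
           status_text = m$status_text,
           action_text = m$action_text,
           benefit_text = m$benefit_text,
           contributors = as.data.frame(m$contributors))
    }),
    healthy_eating = list(
      overall = sc$overall,
      overall_rounded = round_half_up(sc$overall),
      colour = sc$colour,
      components = as.data.frame(comps)
    ),
    group_subheadings = as.list(report$group_subheadings),
    weight_bar = report$weight_bar,
    activity = report$activity,
    config_version = report$config_version,
    timestamp = report$timestamp
  )
}

#' Render a report
#'
#' `json` is lossless and schema-stable (parse it back to recover the report
#' structurally); `text` and `html` are human-readable, with bars written as
#' percentages plus colour names. Output is deterministic for a fixed report
#' object; the timestamp is an injected field, so fixing it (see
#' [build_report()]) makes renders byte-identical across runs.
#'
#' @param report An [build_report()] report.
#' @param format `"json"`, `"text"` or `"html"`.
#' @return A single string.
#' @export
render_report <- function(report, format = c("json", "text", "html")) {
  if (!format[1] %in% c("json", "text", "html")) {
    stop("unknown render format: ", format[1], call. = FALSE)
  }
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(report_to_list(report),
                                         auto_unbox = TRUE, digits = NA,
                                         pretty = TRUE, na = "null")))
  }
  if (format == "text") render_text(report) else render_html(report)
}

render_bar_line <- function(row) {
  sprintf("  %-22s %3d%% [%s]", row$display,
          round_half_up(row$displayed_pct), row$colour)
}

render_text <- function(report) {
  sc <- report$healthy_eating
  lines <- c(report$intro, "")
  for (m in report$messages) {
    lines <- c(lines,
               sprintf("== %s ==", m$component),
               m$status_text, m$action_text, m$benefit_text, "")
  }
  lines <- c(lines,
             sprintf("Healthy Eating Score: %d%% [%s]",
                     round_half_up(sc$overall), sc$colour), "")
  for (grp in c("recommended", "limit")) {
    lines <- c(lines, report$group_subheadings[[grp]])
    rows <- sc$components[sc$components$category == grp, ]
    for (i in seq_len(nrow(rows))) lines <- c(lines, render_bar_line(rows[i, ]))
    lines <- c(lines, "")
  }
  wb <- report$weight_bar
  lines <- c(lines, sprintf(
    "Healthy weight range: %.1f-%.1f kg (current %.1f kg%s)",
    wb$healthy_low, wb$healthy_high, wb$current,
    if (!is.na(wb$out_of_range)) paste0(", ", wb$out_of_range, " range") else ""))
  if (!is.null(report$activity)) {
    a <- report$activity
    lines <- c(lines, sprintf(
      "Physical activity (Baecke): work %.2f, sport %.2f, leisure %.2f, total %.2f (%s)",
      a$work_index, a$sport_index, a$leisure_index, a$total, a$band))
  }
  lines <- c(lines, "", sprintf("Scoring config: %s | Generated: %s",
                                report$config_version, report$timestamp))
  paste(lines, collapse = "\n")
}

render_html <- function(report) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  sc <- report$healthy_eating
  bar <- function(row) sprintf(
    '<div class="bar %s"><span>%s</span><span>%d%%</span></div>',
    row$colour, esc(row$display), round_half_up(row$displayed_pct))
  parts <- c(
    "<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
    "<title>Your personalised nutrition report</title></head><body>",
    sprintf("<p class='intro'>%s</p>", esc(report$intro)))
  for (m in report$messages) {
    parts <- c(parts,
               sprintf("<section class='advice' data-component='%s'>", m$component),
               sprintf("<p>%s</p><p>%s</p><p>%s</p>",
                       esc(m$status_text), esc(m$action_text),
                       esc(m$benefit_text)),
               "</section>")
  }
  parts <- c(parts, sprintf(
    "<h2>Healthy Eating Score: %d%% <span class='%s'>%s</span></h2>",
    round_half_up(sc$overall), sc$colour, sc$colour))
  for (grp in c("recommended", "limit")) {
    parts <- c(parts, sprintf("<h3>%s</h3>",
                              esc(report$group_subheadings[[grp]])))
    rows <- sc$components[sc$components$category == grp, ]
    for (i in seq_len(nrow(rows))) parts <- c(parts, bar(rows[i, ]))
  }
  wb <- report$weight_bar
  parts <- c(parts, sprintf(
    "<p class='weight'>Healthy weight range: %.1f&ndash;%.1f kg (current %.1f kg)</p>",
    wb$healthy_low, wb$healthy_high, wb$current))
  if (!is.null(report$activity)) {
    parts <- c(parts, sprintf(
      "<p class='activity'>Physical activity total %.2f (%s)</p>",
      report$activity$total, report$activity$band))
  }
  parts <- c(parts, sprintf("<footer>%s | %s</footer>",
                            esc(report$config_version), esc(report$timestamp)),
             "</body></html>")
  paste(parts, collapse = "\n")
}

#' @export
print.enutri_report <- function(x, ...) {
  cat(render_text(x), "\n")
  invisible(x)
}
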