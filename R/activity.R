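#' Baecke habitual physical activity indices
#'
#' Scores the 16-item Baecke habitual physical activity questionnaire into
#' three indices (work, sport, leisure), each on a 1-5 scale, plus their
#' total (3-15). All responses are 1-5 ordinal values. Two items are
#' reverse-scored: "sitting at work" (more sitting means less occupational
#' activity) and "watching television" in leisure time.
#'
#' * work = ((6 - sitting) + sum of the 7 other work items) / 8
#' * sport = (sport-intensity composite + 3 other sport items) / 4
#' * leisure = ((6 - television) + 3 other leisure items) / 4
#'
#' @param answers Named list or vector of 16 integer responses in 1..5:
#'   `work_sitting`, `work_standing`, `work_walking`, `work_lifting`,
#'   `work_tired`, `work_sweat`, `work_compare`, `work_physical`;
#'   `sport_score` (the intensity/time composite mapped onto 1-5),
#'   `sport_compare`, `sport_sweat_leisure`, `sport_frequency`;
#'   `leisure_tv`, `leisure_walking`, `leisure_cycling`,
#'   `leisure_minutes_active`.
#' @return A `baecke_result`: list with `work_index`, `sport_index`,
#'   `leisure_index` (each in \[1, 5\]) and `total` (in \[3, 15\]).
#' @export
#' @examples
#' mid <- as.list(stats::setNames(rep(3, 16), enutri:::baecke_items()))
#' baecke_indices(mid)$total  # 9
baecke_indices <- function(answers) {
  items <- baecke_items()
  answers <- as.list(answers)
  miss <- setdiff(items, names(answers))
  if (length(miss)) {
    stop("missing Baecke item(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  v <- vapply(items, function(i) as.numeric(answers[[i]]), numeric(1))
  if (any(is.na(v)) || any(v < 1 | v > 5)) {
    bad <- items[is.na(v) | v < 1 | v > 5]
    stop("Baecke responses must be in 1..5; offending item(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  work_items <- items[1:8]
  sport_items <- items[9:12]
  leisure_items <- items[13:16]
  work <- ((6 - v["work_sitting"]) +
             sum(v[setdiff(work_items, "work_sitting")])) / 8
  sport <- sum(v[sport_items]) / 4
  leisure <- ((6 - v["leisure_tv"]) +
                sum(v[setdiff(leisure_items, "leisure_tv")])) / 4
  structure(
    list(work_index = unname(work),
         sport_index = unname(sport),
         leisure_index = unname(leisure),
         total = unname(work + sport + leisure)),
    class = "baecke_result"
  )
}

baecke_items <- function() {
  c("work_sitting", "work_standing", "work_walking", "work_lifting",
    "work_tired", "work_sweat", "work_compare", "work_physical",
    "sport_score", "sport_compare", "sport_sweat_leisure", "sport_frequency",
    "leisure_tv", "leisure_walking", "leisure_cycling",
    "leisure_minutes_active")
}

#' Activity band for the report's physical-activity bar
#'
#' Bands the Baecke total (3-15) into low / medium / high using configurable
#' thresholds; the defaults are the tertiles of the attainable range.
#'
#' @param result A [baecke_indices()] result.
#' @param thresholds Two ascending cut-offs on the total (default `c(7, 11)`:
#'   low below 7, medium below 11, high otherwise).
#' @return `"low"`, `"medium"` or `"high"`.
#' @export
activity_band <- function(result, thresholds = c(7, 11)) {
  stopifnot(length(thresholds) == 2, diff(thresholds) > 0)
  t <- result$total
  if (t < thresholds[1]) "low" else if (t < thresholds[2]) "medium" else "high"
}
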