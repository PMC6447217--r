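#' Aggregate professional star ratings
#'
#' Summarises 1-5 star ratings of the automated advice on three dimensions
#' (appropriateness, relevance, suitability). Per scenario: the mean and
#' population standard deviation (n denominator — the convention that
#' reproduces summaries such as ratings (5,5,4,5) -> 4.8 +/- 0.4) of each
#' dimension. Overall: the mean of the per-scenario means per dimension
#' (with a balanced design this equals the grand mean), plus the population
#' SD over all records.
#'
#' @param records Data frame with columns `scenario_id`, `rater_id`,
#'   `profession`, `appropriateness`, `relevance`, `suitability`
#'   (integers 1-5); (`scenario_id`, `rater_id`) must be unique.
#' @return List with `per_scenario` (tibble: scenario_id, n, then
#'   `<dim>_mean` / `<dim>_sd` per dimension) and `overall` (tibble:
#'   dimension, mean, sd).
#' @export
aggregate_ratings <- function(records) {
  dims <- c("appropriateness", "relevance", "suitability")
  need <- c("scenario_id", "rater_id", dims)
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("rating records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(records[, c("scenario_id", "rater_id")])) {
    stop("duplicate (scenario, rater) rating record", call. = FALSE)
  }
  for (d in dims) {
    v <- records[[d]]
    if (any(is.na(v)) || any(v < 1 | v > 5)) {
      stop("ratings must be integers in 1..5 (dimension '", d, "')",
           call. = FALSE)
    }
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  per <- dplyr::bind_rows(lapply(
    split(tibble::as_tibble(records), records$scenario_id),
    function(g) {
      row <- tibble::tibble(scenario_id = g$scenario_id[1], n = nrow(g))
      for (d in dims) {
        row[[paste0(d, "_mean")]] <- mean(g[[d]])
        row[[paste0(d, "_sd")]] <- pop_sd(g[[d]])
      }
      row
    }))
  per <- per[order(per$scenario_id), ]
  overall <- tibble::tibble(
    dimension = dims,
    mean = unname(vapply(dims, function(d) mean(per[[paste0(d, "_mean")]]),
                         numeric(1))),
    sd = unname(vapply(dims, function(d) pop_sd(records[[d]]), numeric(1)))
  )
  list(per_scenario = per, overall = overall)
}

#' Overall rating means from a per-scenario summary table
#'
#' When only per-scenario means are available (a published summary rather
#' than raw records), the overall mean per dimension is the mean of the
#' per-scenario means, reported to one decimal.
#'
#' @param summary Data frame with one row per scenario and columns
#'   `<dimension>_mean` for each dimension summarised.
#' @param dims Dimension names (default the three rating dimensions).
#' @return Named numeric of overall means, rounded to one decimal.
#' @export
overall_from_summary <- function(summary,
                                 dims = c("appropriateness", "relevance",
                                          "suitability")) {
  out <- vapply(dims, function(d) {
    col <- paste0(d, "_mean")
    if (!col %in% names(summary)) {
      stop("summary missing column '", col, "'", call. = FALSE)
    }
    round_half_up(mean(summary[[col]]), 1)
  }, numeric(1))
  stats::setNames(out, dims)
}

#' Target-selection frequency table
#'
#' Counts how often each diet-change target was selected, across all
#' selections from one source (the app's automatic targets or the
#' professionals' recommendations), with percentages of the total.
#' Professionals may record "not set"; those entries are excluded from the
#' denominator.
#'
#' @param selections Data frame with columns `source` (`"app"` /
#'   `"professional"`), `scenario_id`, `rater_id` (empty for app rows) and
#'   `target` (free text).
#' @param source Which source to tabulate.
#' @param not_set Labels treated as "no target set" (case-insensitive).
#' @return Tibble `target`, `count`, `pct` (one decimal), sorted by
#'   descending count then target.
#' @export
target_frequencies <- function(selections, source = c("app", "professional"),
                               not_set = c("not set", "none set", "none")) {
  source <- match.arg(source)
  sel <- selections[selections$source == source, , drop = FALSE]
  if (nrow(sel) == 0) stop("no selections for source '", source, "'",
                           call. = FALSE)
  keep <- !(tolower(trimws(sel$target)) %in% tolower(not_set))
  sel <- sel[keep, , drop = FALSE]
  counts <- sort(table(sel$target), decreasing = TRUE)
  out <- tibble::tibble(
    target = names(counts),
    count = as.integer(counts),
    pct = round_half_up(as.integer(counts) / nrow(sel) * 100, 1)
  )
  out[order(-out$count, out$target), ]
}

#' Canonicalise free-text targets through a synonym map
#'
#' @param targets Character vector of free-text target labels.
#' @param synonym_map Named character vector mapping variants to canonical
#'   labels (matched case-insensitively after trimming); labels with no
#'   entry are lower-cased and trimmed but otherwise kept.
#' @return Character vector of canonical labels.
#' @export
canonicalise_targets <- function(targets, synonym_map = character()) {
  key <- tolower(trimws(targets))
  mapped <- unname(synonym_map[key])
  ifelse(is.na(mapped), key, mapped)
}

#' App-vs-professional target concordance
#'
#' For each scenario, compares the app's three automatic targets with each
#' professional's three recommendations (free text, canonicalised through a
#' synonym map): the per-rater overlap |app intersect professional| and the
#' fraction of app targets named by at least one professional. Professional
#' targets with no synonym-map entry are counted as non-matches unless they
#' already equal an app target after normalisation.
#'
#' @param app Data frame of app selections (`scenario_id`, `target`).
#' @param professionals Data frame of professional selections
#'   (`scenario_id`, `rater_id`, `target`).
#' @param synonym_map Named character vector (see
#'   [canonicalise_targets()]).
#' @return List with `per_rater` (tibble: scenario_id, rater_id, overlap,
#'   n_app) and `per_scenario` (tibble: scenario_id, n_app,
#'   n_matched, coverage = fraction of app targets named by >= 1
#'   professional).
#' @export
concordance <- function(app, professionals, synonym_map = character()) {
  app$canon <- canonicalise_targets(app$target, synonym_map)
  professionals$canon <- canonicalise_targets(professionals$target,
                                              synonym_map)
  scen <- sort(unique(app$scenario_id))
  per_rater <- list()
  per_scenario <- list()
  for (s in scen) {
    app_t <- unique(app$canon[app$scenario_id == s])
    pro <- professionals[professionals$scenario_id == s, , drop = FALSE]
    raters <- unique(pro$rater_id)
    for (r in raters) {
      pro_t <- unique(pro$canon[pro$rater_id == r])
      per_rater[[length(per_rater) + 1]] <- tibble::tibble(
        scenario_id = s, rater_id = r,
        overlap = length(intersect(app_t, pro_t)),
        n_app = length(app_t))
    }
    matched <- app_t %in% unique(pro$canon)
    per_scenario[[length(per_scenario) + 1]] <- tibble::tibble(
      scenario_id = s, n_app = length(app_t),
      n_matched = sum(matched),
      coverage = if (length(app_t)) sum(matched) / length(app_t) else NA_real_)
  }
  list(per_rater = dplyr::bind_rows(per_rater),
       per_scenario = dplyr::bind_rows(per_scenario))
}

#' Packaged professional-evaluation summary fixture
#'
#' Per-scenario summary of a 16-scenario professional evaluation of the
#' automated advice: the three targets the app selected for each scenario
#' and the mean +/- SD of the four professional ratings per dimension.
#'
#' @return Tibble with columns `scenario_id`, `target1`-`target3`, and
#'   `<dimension>_mean` / `<dimension>_sd` for the three rating dimensions.
#' @export
load_professional_evaluation <- function() {
  path <- system.file("extdata", "professional_evaluation.csv",
                      package = "enutri")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' App target selections from the packaged evaluation summary, long form
#'
#' @return Tibble with columns `source` (`"app"`), `scenario_id`,
#'   `rater_id` (`NA`), `target`; three rows per scenario.
#' @export
app_target_selections <- function() {
  ev <- load_professional_evaluation()
  long <- lapply(1:3, function(k) {
    tibble::tibble(source = "app", scenario_id = ev$scenario_id,
                   rater_id = NA_character_,
                   target = ev[[paste0("target", k)]])
  })
  out <- dplyr::bind_rows(long)
  out[order(out$scenario_id), ]
}
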