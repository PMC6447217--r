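#' Select the three advice targets
#'
#' The decision engine: the three m-AHEI components with the lowest
#' adherence scores become the report's advice targets, ordered ascending
#' by adherence (weakest first). Ties are broken by the fixed display order
#' (vegetables first ... alcohol last).
#'
#' @param score A [healthy_eating_score()] result.
#' @return Character vector of exactly 3 component names.
#' @export
select_targets <- function(score) {
  comps <- score$components
  if (nrow(comps) != 11) stop("expected 11 component scores", call. = FALSE)
  ord <- order(comps$adherence, seq_len(nrow(comps)))
  comps$name[ord[1:3]]
}

#' Top food contributors to a component
#'
#' Ranks the consumed items mapped to a component by their daily
#' contribution in the component's unit, and reports each with its grams per
#' day. Fewer than `n` items are returned when fewer have positive intake;
#' an empty result signals the message composer to fall back to a generic
#' status sentence (e.g. for a vegetarian's red-meat component).
#'
#' @param profile An [daily_intake()] profile.
#' @param component One of the 11 component names.
#' @param n Maximum number of contributors (default 3).
#' @return Tibble with columns `item_id`, `name`, `contribution` (component
#'   units), `grams_day`, sorted by descending contribution.
#' @export
top_contributors <- function(profile, component, n = 3) {
  if (!component %in% component_names()) {
    stop("unknown m-AHEI component: ", component, call. = FALSE)
  }
  contrib <- profile$contributions[, component]
  keep <- which(contrib > 0)
  if (!length(keep)) {
    return(tibble::tibble(item_id = character(), name = character(),
                          contribution = numeric(), grams_day = numeric()))
  }
  out <- tibble::tibble(
    item_id = profile$items$item_id[keep],
    name = profile$items$name[keep],
    contribution = contrib[keep],
    grams_day = profile$items$grams_day[keep]
  )
  out <- out[order(-out$contribution, out$item_id), ]
  utils::head(out, n)
}

#' Load the advice message templates
#'
#' Templates live as one YAML file per component in a directory; each file
#' gives the component's advice `direction` (`increase` for recommended
#' foods, `decrease` for foods to limit) and the three message paragraphs:
#' `status` (current status), `action` (call to action) and `benefit`
#' (health benefit). Paragraphs may use the placeholders `{name}`, `{pct}`,
#' `{contributors}` and `{unit_hint}`.
#'
#' @param dir Template directory; defaults to the packaged set.
#' @return Named list of template lists, one per component.
#' @export
load_templates <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- system.file("templates", "default", package = "enutri")
  }
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  tpl <- lapply(files, yaml::read_yaml)
  names(tpl) <- vapply(tpl, function(x) x$component %||% "", character(1))
  missing <- setdiff(component_names(), names(tpl))
  if (length(missing)) {
    stop("missing template(s) for component(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (nm in component_names()) {
    t <- tpl[[nm]]
    expected <- if (component_category(nm) == "recommended") "increase" else "decrease"
    if (!identical(t$direction, expected)) {
      stop("template for '", nm, "' must have direction '", expected, "'",
           call. = FALSE)
    }
    for (p in c("status", "action", "benefit")) {
      if (is.null(t[[p]]) || !nzchar(trimws(t[[p]]))) {
        stop("template for '", nm, "' missing paragraph '", p, "'",
             call. = FALSE)
      }
    }
  }
  tpl[component_names()]
}

fill_template <- function(text, values) {
  for (key in names(values)) {
    text <- gsub(paste0("{", key, "}"), values[[key]], text, fixed = TRUE)
  }
  trimws(gsub("\\s+", " ", text))
}

contributors_sentence <- function(contribs) {
  if (nrow(contribs) == 0) return("")
  parts <- sprintf("%s (%s g/day)", contribs$name,
                   format(round_half_up(contribs$grams_day, 1), trim = TRUE))
  paste0("Your top contributors were ",
         paste(parts, collapse = ", "), ".")
}

#' Compose the personalised advice messages
#'
#' Builds the introductory message and exactly three structured message
#' blocks, one per selected target, each with the three-paragraph format:
#' current status (with displayed percentage and top contributors), call to
#' action, and health benefit.
#'
#' @param profile An [daily_intake()] profile.
#' @param score The matching [healthy_eating_score()].
#' @param templates A [load_templates()] template set.
#' @param name Respondent name (used verbatim in the intro).
#' @param n_contributors Contributors listed per message (default 3).
#' @return List with `intro` (string) and `messages` (list of 3 blocks, each
#'   with `component`, `direction`, `displayed_pct`, `status_text`,
#'   `action_text`, `benefit_text` and a `contributors` tibble).
#' @export
compose_report_messages <- function(profile, score, templates, name,
                                    n_contributors = 3) {
  if (!is.character(name) || length(name) != 1 || !nzchar(trimws(name))) {
    stop("respondent name must be a non-empty string", call. = FALSE)
  }
  targets <- select_targets(score)
  intro <- paste0("Hi ", name, ", this is your personalised report. ",
                  "The following messages present the most important diet ",
                  "changes recommended for you.")
  blocks <- lapply(targets, function(comp) {
    tpl <- templates[[comp]]
    if (is.null(tpl)) stop("missing template for component: ", comp,
                           call. = FALSE)
    row <- score$components[score$components$name == comp, ]
    contribs <- top_contributors(profile, comp, n = n_contributors)
    vals <- list(
      name = name,
      pct = as.character(round_half_up(row$displayed_pct)),
      contributors = contributors_sentence(contribs),
      unit_hint = row$unit
    )
    list(component = comp,
         direction = tpl$direction,
         displayed_pct = row$displayed_pct,
         status_text = fill_template(tpl$status, vals),
         action_text = fill_template(tpl$action, vals),
         benefit_text = fill_template(tpl$benefit, vals),
         contributors = contribs)
  })
  list(intro = intro, messages = blocks)
}
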