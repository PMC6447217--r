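#' Adherence score for a single m-AHEI component
#'
#' Adherence is a 0-100 scale where higher is always better; it drives both
#' the overall Healthy Eating Score and the ranking used to select advice
#' targets.
#'
#' * Recommended components rise linearly from 0 at `worst` (conventionally
#'   0 intake) to 100 at `best`, constant at 100 beyond.
#' * Limit components fall linearly from 100 at `best` to 0 at `worst`,
#'   constant beyond.
#' * Alcohol is non-monotone: a trapezoid rising over (0, ideal_low),
#'   100 across the ideal range, falling to 0 at `worst`; exact
#'   non-drinkers (intake 0) receive the configured partial credit.
#'
#' @param intake Daily intake in the component's unit (>= 0).
#' @param spec One component spec from [load_mahei_specs()].
#' @param sex `"M"`/`"F"`; required when the spec is sex-specific.
#' @return Adherence in \[0, 100\].
#' @export
component_adherence <- function(intake, spec, sex = NULL) {
  if (!is.numeric(intake) || is.na(intake) || intake < 0) {
    stop("intake must be a non-negative number (component '",
         spec$name, "')", call. = FALSE)
  }
  r <- resolve_spec(spec, sex)
  if (identical(r$name, "alcohol")) {
    return(alcohol_adherence(intake, r))
  }
  if (r$category == "recommended") {
    100 * min(max((intake - r$worst) / (r$best - r$worst), 0), 1)
  } else {
    100 * min(max((r$worst - intake) / (r$worst - r$best), 0), 1)
  }
}

alcohol_adherence <- function(intake, r) {
  credit <- r$nondrinker_credit %||% 25
  if (intake == 0) return(credit)
  if (intake < r$ideal_low) return(100 * intake / r$ideal_low)
  if (intake <= r$ideal_high) return(100)
  if (intake >= r$worst) return(0)
  100 * (r$worst - intake) / (r$worst - r$ideal_high)
}

#' Displayed status-bar percentage for a component
#'
#' What the report's status bar shows, as opposed to the internal adherence
#' used for ranking. Recommended components display their adherence (percent
#' of target, capped at 100). Foods-to-limit display percent of the
#' recommended *maximum* intake, capped at 100, so a fuller bar means more
#' of a food that should be limited.
#'
#' @inheritParams component_adherence
#' @return Displayed percentage in \[0, 100\].
#' @export
displayed_bar <- function(intake, spec, sex = NULL) {
  if (!is.numeric(intake) || is.na(intake) || intake < 0) {
    stop("intake must be a non-negative number (component '",
         spec$name, "')", call. = FALSE)
  }
  r <- resolve_spec(spec, sex)
  if (r$category == "recommended") {
    component_adherence(intake, spec, sex)
  } else {
    100 * min(intake, r$worst) / r$worst
  }
}

#' Traffic-light colour for a percentage
#'
#' Recommended components and the overall score use thirds: red below 100/3,
#' yellow from 100/3 up to (excluding) 200/3, green at or above 200/3.
#' Foods-to-limit invert the mapping (a full bar is bad): green below 100/3,
#' red strictly above 200/3 — i.e. red only once the displayed intake
#' *exceeds* two-thirds of the recommended maximum — yellow in between.
#'
#' @param pct Percentage in \[0, 100\].
#' @param category `"recommended"`, `"overall"` or `"limit"`.
#' @return `"red"`, `"yellow"` or `"green"`.
#' @export
colour_for <- function(pct, category = c("recommended", "overall", "limit")) {
  category <- match.arg(category)
  if (!is.numeric(pct) || is.na(pct) || pct < 0 || pct > 100) {
    stop("pct must be in [0, 100]", call. = FALSE)
  }
  lo <- 100 / 3
  hi <- 200 / 3
  if (category == "limit") {
    if (pct > hi) "red" else if (pct >= lo) "yellow" else "green"
  } else {
    if (pct < lo) "red" else if (pct < hi) "yellow" else "green"
  }
}

#' Healthy Eating Score: full m-AHEI scoring of an intake profile
#'
#' Scores each of the 11 components and aggregates them into the overall
#' Healthy Eating Score: the unweighted arithmetic mean of the 11 adherence
#' values, presented as a percentage with a traffic-light colour by thirds.
#' Components are returned in the fixed display order, the 7 recommended
#' foods first, then the 4 foods to limit.
#'
#' @param profile An [daily_intake()] profile.
#' @param specs A [load_mahei_specs()] spec set.
#' @param sex `"M"` or `"F"` (two components are sex-specific).
#' @return A `healthy_eating_score`: list with `overall` (0-100), `colour`,
#'   and `components`, a tibble with one row per component (name, display
#'   label, category, intake, unit, adherence, displayed_pct, colour).
#' @export
healthy_eating_score <- function(profile, specs, sex) {
  if (!inherits(specs, "mahei_specs")) {
    stop("specs must come from load_mahei_specs()", call. = FALSE)
  }
  vocab <- mahei_components()
  rows <- lapply(seq_len(nrow(vocab)), function(i) {
    nm <- vocab$name[i]
    sp <- specs$components[[nm]]
    intake <- profile$components[[nm]]
    tibble::tibble(
      name = nm,
      display = vocab$display[i],
      category = vocab$category[i],
      intake = intake,
      unit = sp$unit %||% "",
      adherence = component_adherence(intake, sp, sex),
      displayed_pct = displayed_bar(intake, sp, sex)
    )
  })
  comps <- dplyr::bind_rows(rows)
  comps$colour <- mapply(colour_for, comps$displayed_pct, comps$category)
  overall <- mean(comps$adherence)
  structure(
    list(overall = overall,
         colour = colour_for(overall, "overall"),
         components = comps,
         spec_version = specs$version),
    class = "healthy_eating_score"
  )
}

#' @export
print.healthy_eating_score <- function(x, ...) {
  cat(sprintf("Healthy Eating Score: %d%% (%s)\n",
              round_half_up(x$overall), x$colour))
  df <- x$components
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-22s %-11s %3d%% (%s)\n", df$display[i], df$category[i],
                round_half_up(df$displayed_pct[i]), df$colour[i]))
  }
  invisible(x)
}

# Half-up integer rounding for display only; internal arithmetic stays
# unrounded.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}
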