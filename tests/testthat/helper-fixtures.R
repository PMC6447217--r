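# Shared fixtures and independent oracles.

pkg_foods <- function() {
  load_food_table(system.file("extdata", "foods.csv", package = "enutri"))
}
pkg_specs <- function() load_mahei_specs()
pkg_freqs <- function() load_frequencies()
pkg_templates <- function() load_templates()

# A tiny in-code food table written to a temp CSV.
write_toy_food_csv <- function(rows = NULL, path = tempfile(fileext = ".csv")) {
  if (is.null(rows)) {
    rows <- data.frame(
      item_id = c("veg1", "fruit1", "meat1"),
      name = c("Greens", "Apples", "Mince"),
      portion_g = c(80, 100, 100),
      energy_kcal = c(30, 50, 200),
      free_sugar_g = c(0, 0, 0),
      pufa_g = c(0.1, 0, 0.5),
      salt_g = c(0.05, 0, 0.3),
      alcohol_g = c(0, 0, 0),
      w_vegetables = c(1, 0, 0),
      w_fruits = c(0, 1, 0),
      w_red_meat = c(0, 0, 1)
    )
  }
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

# Minimal intake profile for scoring-only tests: just the component vector.
make_profile <- function(components) {
  stopifnot(setequal(names(components), mahei_components()$name))
  structure(
    list(components = components,
         energy_kcal_day = 2000,
         items = tibble::tibble(item_id = character(), name = character(),
                                occasions_day = numeric(),
                                grams_day = numeric()),
         contributions = matrix(0, 0, 11,
                                dimnames = list(NULL, mahei_components()$name))),
    class = "intake_profile")
}

random_profile <- function() {
  hi <- c(vegetables = 8, fruits = 8, whole_grains = 150, dairy = 5,
          nuts_legumes = 3, healthy_fats = 15, oily_fish = 1,
          sugars = 30, red_meat = 3, salt = 10, alcohol = 5)
  make_profile(stats::setNames(stats::runif(11, 0, hi), names(hi)))
}

# Intakes hitting every component's best target (female cut-points).
perfect_intakes_F <- function(specs = pkg_specs()) {
  v <- stats::setNames(numeric(11), mahei_components()$name)
  for (nm in names(v)) {
    r <- enutri:::resolve_spec(specs$components[[nm]], "F")
    v[nm] <- if (nm == "alcohol") r$ideal_low else r$best
  }
  v
}

# Independent piecewise-linear adherence oracle built on stats::approx.
adherence_oracle <- function(intake, spec, sex) {
  r <- enutri:::resolve_spec(spec, sex)
  if (identical(r$name, "alcohol")) {
    if (intake == 0) return(r$nondrinker_credit)
    xs <- c(0, r$ideal_low, r$ideal_high, r$worst)
    ys <- c(0, 100, 100, 0)
  } else if (r$category == "recommended") {
    xs <- c(r$worst, r$best); ys <- c(0, 100)
  } else {
    xs <- c(r$best, r$worst); ys <- c(100, 0)
  }
  stats::approx(xs, ys, xout = intake, rule = 2)$y
}

# Naive repeated-minimum selection oracle with first-index tie-break.
select_oracle <- function(adherence) {
  sel <- integer()
  for (k in 1:3) {
    best <- NA_integer_
    for (i in seq_along(adherence)) {
      if (i %in% sel) next
      if (is.na(best) || adherence[i] < adherence[best]) best <- i
    }
    sel <- c(sel, best)
  }
  sel
}

make_score <- function(adherence) {
  comps <- mahei_components()
  comps$adherence <- adherence
  comps$intake <- 0
  comps$unit <- ""
  comps$displayed_pct <- adherence
  comps$colour <- "red"
  structure(list(overall = mean(adherence), colour = "yellow",
                 components = comps, spec_version = "test"),
            class = "healthy_eating_score")
}

baecke_mid_answers <- function(value = 3) {
  as.list(stats::setNames(rep(value, 16), enutri:::baecke_items()))
}

toy_rating_records <- function() {
  tibble::tibble(
    scenario_id = rep(1:2, each = 4),
    rater_id = rep(c("RD01", "RD02", "RN01", "RN02"), 2),
    profession = rep(c("RD", "RD", "RN", "RN"), 2),
    appropriateness = c(5, 5, 4, 5, 3, 3, 3, 3),
    relevance = c(4, 4, 4, 4, 2, 3, 4, 5),
    suitability = c(5, 4, 3, 2, 1, 2, 3, 4)
  )
}
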