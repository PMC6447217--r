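#' The 2^4 factorial evaluation scenarios
#'
#' Sixteen scenarios crossing sex (M/F), age band (<40 / >40), BMI band
#' (Ideal 18.5-24.9 / Overweight >25) and diet-quality band (m-AHEI <40 /
#' >60), in the canonical order: the diet band varies fastest, then BMI,
#' then age, then sex (so scenario 1 is M, <40, Ideal, <40 and scenario 16
#' is F, >40, Overweight, >60).
#'
#' @return Tibble with columns `id` (1-16), `sex`, `age_band`, `bmi_band`,
#'   `mahei_band`.
#' @export
factorial_scenarios <- function() {
  grid <- expand.grid(
    mahei_band = c("<40", ">60"),
    bmi_band = c("Ideal", "Overweight"),
    age_band = c("<40", ">40"),
    sex = c("M", "F"),
    stringsAsFactors = FALSE
  )
  tibble::tibble(
    id = seq_len(nrow(grid)),
    sex = grid$sex,
    age_band = grid$age_band,
    bmi_band = grid$bmi_band,
    mahei_band = grid$mahei_band
  )
}

# Representative item per component: the most concentrated source in the
# food table. "Neutral" items (no food-group weight, no alcohol, little
# sugar/salt) supply energy, PUFA and salt without disturbing the others.
covering_set <- function(foods) {
  group_components <- setdiff(component_names(),
                              c("sugars", "healthy_fats", "salt", "alcohol"))
  pick <- stats::setNames(vector("list", 11), component_names())
  for (gc in group_components) {
    w <- foods[[paste0("w_", gc)]]
    if (all(w <= 0)) {
      stop("infeasible food table: no item mapped to component '", gc, "'",
           call. = FALSE)
    }
    pick[[gc]] <- foods[which.max(w), ]
  }
  wsum <- rowSums(as.matrix(foods[, paste0("w_", group_components)]))
  neutral <- foods[wsum == 0 & foods$alcohol_g == 0, ]
  plain <- neutral[neutral$free_sugar_g < 1 & neutral$salt_g < 1, ]
  for (nm in c("sugars", "healthy_fats", "salt", "alcohol")) {
    cand <- switch(nm,
      sugars = neutral[which.max(neutral$free_sugar_g), ],
      healthy_fats = plain[which.max(plain$pufa_g), ],
      salt = neutral[which.max(neutral$salt_g), ],
      alcohol = foods[which.max(foods$alcohol_g), ])
    amount <- switch(nm,
      sugars = cand$free_sugar_g, healthy_fats = cand$pufa_g,
      salt = cand$salt_g, alcohol = cand$alcohol_g / 10)
    if (nrow(cand) == 0 || length(amount) == 0 || amount <= 0) {
      stop("infeasible food table: no item mapped to component '", nm, "'",
           call. = FALSE)
    }
    pick[[nm]] <- cand
  }
  staple <- plain[which.max(plain$energy_kcal), ]
  if (nrow(staple) == 0) {
    stop("infeasible food table: no neutral energy staple", call. = FALSE)
  }
  list(components = pick, staple = staple)
}

# Snap a desired occasions/day onto the categorical frequency grid
# (frequency label x portion multiplier in {0.5, 1, 2, 3}).
closest_answer <- function(occ, freqs, mults = c(0.5, 1, 2, 3)) {
  if (occ <= 0) {
    zero <- freqs$label[freqs$per_day == 0]
    return(list(frequency = if (length(zero)) zero[1] else freqs$label[1],
                portion_multiplier = 1))
  }
  grid <- expand.grid(f = seq_len(nrow(freqs)), m = mults)
  vals <- freqs$per_day[grid$f] * grid$m
  i <- which.min(abs(vals - occ))
  list(frequency = freqs$label[grid$f[i]], portion_multiplier = grid$m[i])
}

sample_band_fractions <- function(band) {
  comps <- mahei_components()
  f <- stats::setNames(numeric(11), comps$name)
  for (i in seq_len(11)) {
    f[i] <- if (band == "<40") {
      stats::runif(1, 0, 0.5)
    } else if (comps$category[i] == "limit") {
      stats::runif(1, 0.9, 1)   # foods-to-limit near best in the high band
    } else {
      stats::runif(1, 0.6, 1)
    }
  }
  f
}

#' Simulate a synthetic FFQ respondent for a scenario
#'
#' Inverts the scoring model: per-component target fractions are sampled
#' from band-specific ranges (diet band `<40`: adherence fractions
#' ~ U(0, 0.5); `>60`: U(0.6, 1) with foods-to-limit near their best), the
#' implied intakes are back-solved onto the categorical frequency grid
#' through a minimal covering set of food items, and the candidate is
#' rejection-resampled until the re-scored Healthy Eating Score lands in
#' the scenario's band. Sex, age, height and weight (solved from a BMI
#' sampled in the scenario's band) complete the respondent.
#'
#' @param scenario One row of [factorial_scenarios()] (or a list with the
#'   same fields).
#' @param foods Food table covering all 11 components.
#' @param specs An m-AHEI spec set.
#' @param seed Integer seed; identical seeds reproduce the respondent.
#' @param freqs Frequency dialect.
#' @param max_attempts Rejection-resampling cap (default 1000).
#' @return An [ffq_response()] whose profile satisfies the scenario bands.
#' @export
simulate_respondent <- function(scenario, foods, specs, seed,
                                freqs = load_frequencies(),
                                max_attempts = 1000) {
  if (is.data.frame(scenario)) scenario <- as.list(scenario[1, ])
  set.seed(seed)
  cov <- covering_set(foods)
  sex <- scenario$sex

  age <- if (scenario$age_band == "<40") sample(25:39, 1) else sample(41:65, 1)
  height <- round(stats::rnorm(1, if (sex == "M") 1.78 else 1.64, 0.06), 2)
  height <- min(max(height, 1.50), 1.95)
  bmi <- if (scenario$bmi_band == "Ideal") {
    stats::runif(1, 19, 24.5)
  } else {
    stats::runif(1, 25.5, 32)
  }
  weight <- round(bmi * height^2, 1)
  pool <- if (sex == "M") {
    c("John", "David", "Mark", "Ahmed", "Tom", "Lukas", "Raj", "Peter")
  } else {
    c("Jane", "Sarah", "Priya", "Emma", "Lucy", "Fatima", "Anna", "Claire")
  }
  name <- sample(pool, 1)
  energy_target <- if (sex == "M") 2500 else 2000

  band <- scenario$mahei_band
  in_band <- function(s) if (band == "<40") s < 40 else s > 60
  achieved <- c(Inf, -Inf)

  for (attempt in seq_len(max_attempts)) {
    f <- sample_band_fractions(band)
    answers <- simulate_answers(f, cov, specs, sex, energy_target, freqs)
    resp <- ffq_response(name, sex, age, height, weight, answers)
    prof <- daily_intake(resp, foods, freqs)
    sc <- healthy_eating_score(prof, specs, sex)$overall
    achieved <- c(min(achieved[1], sc), max(achieved[2], sc))
    if (in_band(sc)) return(resp)
  }
  stop(sprintf(
    "could not hit m-AHEI band %s in %d attempts (achieved scores %.1f-%.1f)",
    band, max_attempts, achieved[1], achieved[2]), call. = FALSE)
}

simulate_answers <- function(f, cov, specs, sex, energy_target, freqs) {
  comps <- mahei_components()
  rows <- list()
  energy_so_far <- 0
  pufa_so_far <- 0
  add <- function(item, occ) {
    a <- closest_answer(occ, freqs)
    occ_real <- freqs$per_day[freqs$label == a$frequency] * a$portion_multiplier
    energy_so_far <<- energy_so_far + occ_real * item$energy_kcal
    pufa_so_far <<- pufa_so_far + occ_real * item$pufa_g
    rows[[length(rows) + 1]] <<- tibble::tibble(
      item_id = item$item_id, frequency = a$frequency,
      portion_multiplier = a$portion_multiplier)
  }

  for (nm in setdiff(comps$name, c("healthy_fats", "sugars"))) {
    sp <- resolve_spec(specs$components[[nm]], sex)
    item <- cov$components[[nm]]
    target <- if (nm == "alcohol") {
      if (f[nm] >= 0.6) {
        stats::runif(1, sp$ideal_low, sp$ideal_high)
      } else {
        sp$ideal_high + (1 - f[nm]) * (sp$worst - sp$ideal_high)
      }
    } else if (sp$category == "recommended") {
      sp$worst + f[nm] * (sp$best - sp$worst)
    } else {
      sp$worst - f[nm] * (sp$worst - sp$best)
    }
    per_portion <- switch(nm,
      salt = item$salt_g,
      alcohol = item$alcohol_g / 10,
      item[[paste0("w_", nm)]])
    add(item, target / per_portion)
  }

  # %-energy components: invert against the sex-specific energy anchor,
  # then top energy up to the anchor with the neutral staple.
  sp <- resolve_spec(specs$components[["sugars"]], sex)
  sugar_pct <- sp$worst - f[["sugars"]] * (sp$worst - sp$best)
  sugar_item <- cov$components[["sugars"]]
  add(sugar_item, (sugar_pct / 100 * energy_target / 4) / sugar_item$free_sugar_g)

  sp <- resolve_spec(specs$components[["healthy_fats"]], sex)
  pufa_pct <- sp$worst + f[["healthy_fats"]] * (sp$best - sp$worst)
  fat_item <- cov$components[["healthy_fats"]]
  pufa_target <- pufa_pct / 100 * energy_target / 9
  add(fat_item, max(0, pufa_target - pufa_so_far) / fat_item$pufa_g)

  staple <- cov$staple
  add(staple, max(0, energy_target - energy_so_far) / staple$energy_kcal)

  dplyr::bind_rows(rows)
}

#' Balanced assignment of scenarios to professional raters
#'
#' Each scenario is evaluated by `n_rd` Registered Dietitians and `n_rn`
#' Registered Nutritionists; each rater receives exactly two scenarios. The
#' default design (16 scenarios, 2 RD + 2 RN each) therefore needs 16 RD and
#' 16 RN and yields 16 x 4 = 64 scenario-evaluations.
#'
#' @param scenarios A [factorial_scenarios()] table (or any scenario table
#'   with an `id` column).
#' @param n_rd,n_rn Raters per scenario from each profession.
#' @param seed Optional seed for the reproducible scenario shuffle.
#' @return Tibble with columns `scenario_id`, `rater_id`, `profession`;
#'   one row per scenario-evaluation.
#' @export
evaluation_design <- function(scenarios = factorial_scenarios(),
                              n_rd = 2, n_rn = 2, seed = NULL) {
  ids <- scenarios$id
  n <- length(ids)
  if (!is.null(seed)) {
    set.seed(seed)
    ids <- sample(ids)
  }
  one_profession <- function(per_scenario, prefix) {
    if ((n * per_scenario) %% 2 != 0) {
      stop("infeasible design: ", n, " scenarios x ", per_scenario,
           " raters each cannot be split into 2-scenario workloads",
           call. = FALSE)
    }
    n_raters <- n * per_scenario / 2
    seq_all <- unlist(lapply(seq_len(per_scenario) - 1, function(k) {
      if (k == 0) ids else c(ids[-seq_len(k)], ids[seq_len(k)])  # rotate
    }))
    tibble::tibble(
      scenario_id = seq_all,
      rater_id = sprintf("%s%02d", prefix, rep(seq_len(n_raters), each = 2)),
      profession = prefix
    )
  }
  out <- dplyr::bind_rows(one_profession(n_rd, "RD"),
                          one_profession(n_rn, "RN"))
  out[order(out$scenario_id, out$profession, out$rater_id), ]
}
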