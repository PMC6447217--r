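#' Load a food composition / food-group mapping table
#'
#' One row per FFQ line item. Required columns: `item_id`, `name`,
#' `portion_g` (grams per standard portion) and per-portion nutrient amounts
#' `energy_kcal`, `free_sugar_g`, `pufa_g`, `salt_g`, `alcohol_g`. Food-group
#' membership is encoded as one optional column per recommended-food
#' component, named `w_<component>` (e.g. `w_vegetables`), giving the amount
#' contributed per portion in that component's unit (servings, or grams for
#' whole grains). The four nutrient-driven components (sugars, healthy fats,
#' salt, alcohol) are derived from the nutrient columns, so they take no
#' `w_` column.
#'
#' @param path CSV file (UTF-8, header row).
#' @return A `food_table`: a tibble with one row per item and a zeroed
#'   column for every absent food-group component.
#' @export
load_food_table <- function(path) {
  if (!file.exists(path)) stop("food table not found: ", path, call. = FALSE)
  ft <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, fileEncoding = "UTF-8")
  required <- c("item_id", "name", "portion_g", "energy_kcal",
                "free_sugar_g", "pufa_g", "salt_g", "alcohol_g")
  miss <- setdiff(required, names(ft))
  if (length(miss)) {
    stop("food table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  group_components <- setdiff(component_names(),
                              c("sugars", "healthy_fats", "salt", "alcohol"))
  wcols <- grep("^w_", names(ft), value = TRUE)
  bad <- setdiff(sub("^w_", "", wcols), group_components)
  if (length(bad)) {
    stop("not an m-AHEI food-group component: ",
         paste(bad, collapse = ", "),
         " (valid: ", paste(group_components, collapse = ", "), ")",
         call. = FALSE)
  }
  for (gc in group_components) {
    col <- paste0("w_", gc)
    if (!col %in% names(ft)) ft[[col]] <- 0
  }
  if (anyDuplicated(ft$item_id)) {
    stop("duplicate item_id(s): ",
         paste(unique(ft$item_id[duplicated(ft$item_id)]), collapse = ", "),
         call. = FALSE)
  }
  num_cols <- c("portion_g", "energy_kcal", "free_sugar_g", "pufa_g",
                "salt_g", "alcohol_g", paste0("w_", group_components))
  for (col in num_cols) {
    v <- ft[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      stop("column '", col, "' must be numeric and complete", call. = FALSE)
    }
  }
  bad_portion <- ft$item_id[ft$portion_g <= 0]
  if (length(bad_portion)) {
    stop("portion_g must be > 0; offending item(s): ",
         paste(bad_portion, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(num_cols, "portion_g")) {
    neg <- ft$item_id[ft[[col]] < 0]
    if (length(neg)) {
      stop("negative ", col, " for item(s): ", paste(neg, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(tibble::as_tibble(ft), class = c("food_table", class(tibble::tibble())))
}

#' Load a frequency-category dialect
#'
#' FFQ frequency grids are categorical; each category maps to a daily
#' multiplier (occasions/day), conventionally the midpoint of the category
#' range (with a month taken as 30.44 days). The packaged default dialect
#' ships as an editable CSV.
#'
#' @param path CSV with columns `label`, `per_day`. Defaults to the packaged
#'   dialect.
#' @return A tibble with unique labels and `per_day >= 0`.
#' @export
load_frequencies <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "frequencies.csv", package = "enutri")
  }
  fr <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("label", "per_day") %in% names(fr))) {
    stop("frequency dialect needs columns 'label' and 'per_day'", call. = FALSE)
  }
  if (anyDuplicated(fr$label)) stop("duplicate frequency labels", call. = FALSE)
  if (any(fr$per_day < 0) || anyNA(fr$per_day)) {
    stop("per_day must be >= 0", call. = FALSE)
  }
  tibble::as_tibble(fr)
}

#' Construct an FFQ response
#'
#' @param name Respondent name (non-empty).
#' @param sex `"M"` or `"F"`.
#' @param age Years (> 0).
#' @param height Metres (> 0).
#' @param weight Kilograms (> 0).
#' @param answers Data frame with columns `item_id`, `frequency` (a dialect
#'   label) and `portion_multiplier` (scalar on the standard portion,
#'   e.g. 0.5, 1, 2, 3).
#' @param activity Optional named list or vector of 16 Baecke questionnaire
#'   responses (see [baecke_indices()]).
#' @return An object of class `ffq_response`.
#' @export
ffq_response <- function(name, sex, age, height, weight, answers,
                         activity = NULL) {
  if (!is.character(name) || length(name) != 1 || !nzchar(trimws(name))) {
    stop("respondent name must be a non-empty string", call. = FALSE)
  }
  if (!sex %in% c("M", "F")) stop("sex must be 'M' or 'F'", call. = FALSE)
  if (!is.numeric(age) || age <= 0) stop("age must be > 0", call. = FALSE)
  if (!is.numeric(height) || height <= 0) stop("height must be > 0", call. = FALSE)
  if (!is.numeric(weight) || weight <= 0) stop("weight must be > 0", call. = FALSE)
  answers <- tibble::as_tibble(answers)
  need <- c("item_id", "frequency", "portion_multiplier")
  miss <- setdiff(need, names(answers))
  if (length(miss)) {
    stop("answers missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(answers$portion_multiplier < 0)) {
    stop("portion_multiplier must be >= 0", call. = FALSE)
  }
  structure(
    list(respondent = list(name = name, sex = sex, age = age,
                           height = height, weight = weight),
         answers = answers,
         activity = activity),
    class = "ffq_response"
  )
}

#' Read / write an FFQ response as JSON
#'
#' The JSON layout (documented in
#' `system.file("schemas", "ffq_response.schema.json", package = "enutri")`)
#' holds the respondent characteristics, the answer list and optional Baecke
#' activity answers in one document.
#'
#' @param path JSON file path.
#' @return [read_ffq()] returns an `ffq_response`; [write_ffq()] its path,
#'   invisibly.
#' @export
read_ffq <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  r <- doc$respondent
  if (is.null(r)) stop("FFQ JSON missing 'respondent' block", call. = FALSE)
  act <- doc$activity
  if (!is.null(act)) act <- as.list(act)
  ffq_response(r$name, r$sex, r$age, r$height, r$weight,
               tibble::as_tibble(doc$answers), activity = act)
}

#' @rdname read_ffq
#' @param response An `ffq_response`.
#' @export
write_ffq <- function(response, path) {
  doc <- list(respondent = response$respondent,
              answers = response$answers)
  if (!is.null(response$activity)) doc$activity <- response$activity
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Convert an FFQ response to daily intakes per m-AHEI component
#'
#' For each answer, occasions/day = frequency multiplier x portion
#' multiplier; grams/day = occasions/day x portion grams. Component intakes
#' are summed over items: the seven food-group components from their
#' per-portion weights, salt from `salt_g` (g/day), alcohol from
#' `alcohol_g` / 10 (drinks/day, 1 drink = 10 g ethanol). Free sugars and
#' healthy fats (PUFA) are expressed as a percentage of dietary energy,
#' using 4 kcal/g for sugar and 9 kcal/g for PUFA.
#'
#' @param response An [ffq_response()].
#' @param foods A [load_food_table()] table covering every answered item.
#' @param freqs A frequency dialect ([load_frequencies()]).
#' @return An `intake_profile`: list with `components` (named numeric of
#'   length 11, in component units), `energy_kcal_day`,
#'   `free_sugar_g_day`, `pufa_g_day`, `free_sugar_pct_energy`,
#'   `pufa_pct_energy`, an `items` tibble (per-item occasions and grams per
#'   day) and a `contributions` matrix (items x 11, component units) used
#'   for contributor ranking.
#' @export
daily_intake <- function(response, foods, freqs = load_frequencies()) {
  ans <- response$answers
  unknown <- setdiff(ans$item_id, foods$item_id)
  if (length(unknown)) {
    stop("answer item(s) not in food table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  fidx <- match(ans$frequency, freqs$label)
  if (anyNA(fidx)) {
    stop("unknown frequency label(s): ",
         paste(unique(ans$frequency[is.na(fidx)]), collapse = ", "),
         call. = FALSE)
  }
  rows <- foods[match(ans$item_id, foods$item_id), ]
  occ <- freqs$per_day[fidx] * ans$portion_multiplier
  grams <- occ * rows$portion_g
  energy <- sum(occ * rows$energy_kcal)
  sugar_g <- sum(occ * rows$free_sugar_g)
  pufa_g <- sum(occ * rows$pufa_g)

  comp <- stats::setNames(numeric(11), component_names())
  group_components <- setdiff(component_names(),
                              c("sugars", "healthy_fats", "salt", "alcohol"))
  contrib <- matrix(0, nrow = nrow(ans), ncol = 11,
                    dimnames = list(NULL, component_names()))
  for (gc in group_components) {
    contrib[, gc] <- occ * rows[[paste0("w_", gc)]]
  }
  contrib[, "salt"] <- occ * rows$salt_g
  contrib[, "alcohol"] <- occ * rows$alcohol_g / 10
  # grams of sugar/PUFA per item; converted to % energy at profile level
  contrib[, "sugars"] <- occ * rows$free_sugar_g
  contrib[, "healthy_fats"] <- occ * rows$pufa_g
  for (nm in component_names()) comp[nm] <- sum(contrib[, nm])

  if (energy <= 0 && (sugar_g > 0 || pufa_g > 0)) {
    stop("zero total energy with nonzero sugar/PUFA intake", call. = FALSE)
  }
  sugar_pct <- if (energy > 0) sugar_g * 4 / energy * 100 else 0
  pufa_pct <- if (energy > 0) pufa_g * 9 / energy * 100 else 0
  comp["sugars"] <- sugar_pct
  comp["healthy_fats"] <- pufa_pct

  structure(
    list(components = comp,
         energy_kcal_day = energy,
         free_sugar_g_day = sugar_g,
         pufa_g_day = pufa_g,
         free_sugar_pct_energy = sugar_pct,
         pufa_pct_energy = pufa_pct,
         items = tibble::tibble(item_id = ans$item_id,
                                name = rows$name,
                                occasions_day = occ,
                                grams_day = grams),
         contributions = contrib),
    class = "intake_profile"
  )
}
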