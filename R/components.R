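#' The m-AHEI component vocabulary
#'
#' The modified Alternative Healthy Eating Index (m-AHEI) used by the advice
#' engine has exactly 11 components: 7 "recommended foods" (intake should
#' rise towards a target) followed by 4 "foods to limit" (intake should stay
#' below a maximum). The fixed display order below is also the tie-break
#' order used when ranking components for advice selection.
#'
#' @return A tibble with columns `name` (machine slug), `display` (label),
#'   and `category` (`"recommended"` or `"limit"`), in fixed display order.
#' @export
#' @examples
#' mahei_components()
mahei_components <- function() {
  tibble::tibble(
    name = c(
      "vegetables", "fruits", "whole_grains", "dairy", "nuts_legumes",
      "healthy_fats", "oily_fish",
      "sugars", "red_meat", "salt", "alcohol"
    ),
    display = c(
      "Vegetables", "Fruits", "Whole grains", "Dairy products",
      "Nuts & legumes", "Healthy fats", "Oily fish",
      "Sugars", "Red & processed meat", "Salt", "Alcohol"
    ),
    category = c(rep("recommended", 7), rep("limit", 4))
  )
}

component_names <- function() mahei_components()$name

component_category <- function(name) {
  comps <- mahei_components()
  comps$category[match(name, comps$name)]
}

#' Load an m-AHEI component specification set
#'
#' Reads the scoring configuration: for every component its category, unit,
#' the intake earning full adherence (`best`), the intake earning zero
#' (`worst`), and — for the alcohol component — the ideal drinking range and
#' non-drinker partial credit. `best`/`worst` may be given per sex (a map
#' with keys `M`/`F`) for sex-specific components (whole grains, alcohol).
#'
#' All cut-points are configuration, not code: the scoring engine is defined
#' over any valid spec set. The packaged default
#' (`system.file("extdata", "mahei_specs.yaml", package = "enutri")`) adapts
#' AHEI-2010 cut-points, with free sugars and healthy fats (PUFA) scored as
#' a percentage of dietary energy.
#'
#' @param path Path to a YAML spec file. Defaults to the packaged config.
#' @return An object of class `mahei_specs`: a list with `version` (string)
#'   and `components` (named list of per-component spec lists).
#' @export
load_mahei_specs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mahei_specs.yaml", package = "enutri")
  }
  if (!file.exists(path)) stop("spec file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$version) || !nzchar(raw$version)) {
    stop("mahei spec config must carry a 'version' string", call. = FALSE)
  }
  comps <- raw$components
  names(comps) <- vapply(comps, function(x) x$name %||% "", character(1))
  validate_mahei_specs(comps)
  structure(list(version = raw$version, components = comps),
            class = "mahei_specs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_mahei_specs <- function(comps) {
  vocab <- mahei_components()
  missing <- setdiff(vocab$name, names(comps))
  extra <- setdiff(names(comps), vocab$name)
  if (length(missing)) {
    stop("spec set missing components: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(extra)) {
    stop("unknown m-AHEI components in spec set: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  for (nm in vocab$name) {
    sp <- comps[[nm]]
    cat_expected <- vocab$category[vocab$name == nm]
    if (!identical(sp$category, cat_expected)) {
      stop("component '", nm, "' must have category '", cat_expected, "'",
           call. = FALSE)
    }
    for (sex in c("M", "F")) {
      r <- resolve_spec(sp, sex)
      if (nm == "alcohol") {
        stopifnot(r$ideal_low > 0, r$ideal_high >= r$ideal_low,
                  r$worst > r$ideal_high)
      } else if (r$category == "recommended") {
        if (!(r$best > r$worst)) {
          stop("recommended component '", nm, "' needs best > worst",
               call. = FALSE)
        }
      } else {
        if (!(r$worst > r$best)) {
          stop("limit component '", nm, "' needs worst > best",
               call. = FALSE)
        }
      }
    }
  }
  invisible(comps)
}

# Resolve sex-specific fields ({M: x, F: y} maps) to plain numbers.
resolve_spec <- function(spec, sex = NULL) {
  pick <- function(v) {
    if (is.list(v)) {
      if (is.null(sex)) {
        stop("sex required for sex-specific component '", spec$name, "'",
             call. = FALSE)
      }
      if (!sex %in% names(v)) {
        stop("no value for sex '", sex, "' in component '", spec$name, "'",
             call. = FALSE)
      }
      v[[sex]]
    } else v
  }
  out <- spec
  for (f in c("best", "worst", "ideal_low", "ideal_high")) {
    if (!is.null(spec[[f]])) out[[f]] <- as.numeric(pick(spec[[f]]))
  }
  out
}
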