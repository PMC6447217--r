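specs <- pkg_specs()

test_that("adherence hits its endpoints and interpolates linearly", {
  veg <- specs$components$vegetables
  expect_equal(component_adherence(5, veg), 100)    # at target
  expect_equal(component_adherence(9, veg), 100)    # beyond target, capped
  expect_equal(component_adherence(0, veg), 0)
  expect_equal(component_adherence(2.5, veg), 50)

  salt <- specs$components$salt
  expect_equal(component_adherence(0, salt), 100)   # limit best = 0
  expect_equal(component_adherence(6, salt), 0)
  expect_equal(component_adherence(4, salt), 100 * (6 - 4) / 6)
  expect_equal(component_adherence(10, salt), 0)    # beyond worst, floored

  # recommended component with a nonzero floor (PUFA % energy: 2 -> 10)
  hf <- specs$components$healthy_fats
  expect_equal(component_adherence(2, hf), 0)
  expect_equal(component_adherence(10, hf), 100)
  expect_equal(component_adherence(6, hf), 50)

  expect_error(component_adherence(-1, veg), "non-negative")
})

test_that("alcohol is a trapezoid with non-drinker partial credit", {
  alc <- specs$components$alcohol
  expect_equal(component_adherence(0, alc, "F"), 25)     # non-drinker credit
  expect_equal(component_adherence(1, alc, "F"), 100)    # in ideal range
  expect_equal(component_adherence(2, alc, "M"), 100)    # sex-specific range
  expect_equal(component_adherence(2.5, alc, "F"), 0)
  expect_equal(component_adherence(2, alc, "F"), 50)     # falling edge
  expect_equal(component_adherence(0.25, alc, "F"), 50)  # rising edge
  expect_error(component_adherence(1, alc), "sex")
})

test_that("sex-specific whole-grain targets resolve per sex", {
  wg <- specs$components$whole_grains
  expect_equal(component_adherence(75, wg, "F"), 100)
  expect_equal(component_adherence(75, wg, "M"), 100 * 75 / 90)
  expect_error(component_adherence(50, wg), "sex")
})

test_that("displayed bars show percent-of-target or percent-of-maximum", {
  veg <- specs$components$vegetables
  salt <- specs$components$salt
  expect_equal(displayed_bar(3.75, veg), 75)               # 75% of target
  expect_equal(displayed_bar(6, salt), 100)                # at the maximum
  expect_equal(displayed_bar(9, salt), 100)                # capped
  expect_equal(displayed_bar(6 * 0.7, salt), 70)           # 70% of maximum
  expect_identical(colour_for(70, "limit"), "red")         # exceeds 2/3
  alc <- specs$components$alcohol
  expect_equal(displayed_bar(1.25, alc, "F"), 50)          # percent of worst
})

test_that("traffic-light thirds, with inverted limit semantics", {
  expect_identical(colour_for(0, "recommended"), "red")
  expect_identical(colour_for(100 / 3 - 1e-9, "recommended"), "red")
  expect_identical(colour_for(100 / 3, "recommended"), "yellow")
  expect_identical(colour_for(50, "overall"), "yellow")
  expect_identical(colour_for(200 / 3, "recommended"), "green")
  expect_identical(colour_for(100, "recommended"), "green")

  expect_identical(colour_for(0, "limit"), "green")
  expect_identical(colour_for(100 / 3 - 1e-9, "limit"), "green")
  expect_identical(colour_for(100 / 3, "limit"), "yellow")
  # red only strictly beyond two-thirds of the maximum
  expect_identical(colour_for(200 / 3, "limit"), "yellow")
  expect_identical(colour_for(200 / 3 + 1e-9, "limit"), "red")
  expect_identical(colour_for(100, "limit"), "red")

  expect_error(colour_for(101, "overall"), "0, 100")
})

test_that("the overall score is the mean of 11 adherences", {
  perfect <- make_profile(perfect_intakes_F())
  s <- healthy_eating_score(perfect, specs, "F")
  expect_equal(s$overall, 100)
  expect_identical(s$colour, "green")
  expect_equal(nrow(s$components), 11)
  expect_identical(s$components$category,
                   c(rep("recommended", 7), rep("limit", 4)))

  worst <- perfect_intakes_F()
  worst[] <- 0
  for (nm in c("sugars", "red_meat", "salt", "alcohol")) {
    worst[nm] <- enutri:::resolve_spec(specs$components[[nm]], "F")$worst
  }
  s0 <- healthy_eating_score(make_profile(worst), specs, "F")
  # alcohol at worst scores 0, every other component too
  expect_equal(s0$overall, 0)
  expect_identical(s0$colour, "red")

  # seven components at 100, four at 0 -> 700/11
  mixed <- perfect_intakes_F()
  for (nm in c("sugars", "red_meat", "salt", "alcohol")) {
    mixed[nm] <- enutri:::resolve_spec(specs$components[[nm]], "F")$worst
  }
  sm <- healthy_eating_score(make_profile(mixed), specs, "F")
  expect_equal(sm$overall, 700 / 11, tolerance = 1e-12)
  expect_equal(round(sm$overall, 2), 63.64)
})

test_that("closed-form adherence matches a piecewise-linear oracle", {
  set.seed(101)
  for (k in 1:1000) {
    p <- random_profile()
    sex <- sample(c("M", "F"), 1)
    for (nm in mahei_components()$name) {
      sp <- specs$components[[nm]]
      expect_equal(component_adherence(p$components[[nm]], sp, sex),
                   adherence_oracle(p$components[[nm]], sp, sex),
                   tolerance = 1e-9)
    }
  }
})

test_that("adherence is monotone in intake within each category", {
  grid <- seq(0, 1, length.out = 21)
  for (nm in mahei_components()$name) {
    if (nm == "alcohol") next  # non-monotone by design
    sp <- specs$components[[nm]]
    r <- enutri:::resolve_spec(sp, "M")
    xs <- grid * 1.5 * max(r$best, r$worst)
    ys <- vapply(xs, component_adherence, numeric(1), spec = sp, sex = "M")
    d <- diff(ys)
    if (r$category == "recommended") {
      expect_true(all(d >= -1e-12), info = nm)
      expect_equal(ys[xs >= r$best], rep(100, sum(xs >= r$best)))
    } else {
      expect_true(all(d <= 1e-12), info = nm)
      expect_equal(ys[xs >= r$worst], rep(0, sum(xs >= r$worst)))
    }
  }
})

test_that("spec config validation rejects broken component sets", {
  path <- tempfile(fileext = ".yaml")
  raw <- yaml::read_yaml(system.file("extdata", "mahei_specs.yaml",
                                     package = "enutri"))
  broken <- raw
  broken$components <- broken$components[-1]
  yaml::write_yaml(broken, path)
  expect_error(load_mahei_specs(path), "vegetables")

  broken <- raw
  broken$components[[10]]$best <- 7   # salt best above worst 6
  yaml::write_yaml(broken, path)
  expect_error(load_mahei_specs(path), "salt")

  broken <- raw
  broken$version <- NULL
  yaml::write_yaml(broken, path)
  expect_error(load_mahei_specs(path), "version")
})
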