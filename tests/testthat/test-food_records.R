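test_that("food table loads, validates and rejects malformed rows", {
  path <- write_toy_food_csv()
  ft <- load_food_table(path)
  expect_s3_class(ft, "food_table")
  expect_equal(nrow(ft), 3)
  # absent food-group columns are zero-filled
  expect_true(all(ft$w_oily_fish == 0))

  bad <- utils::read.csv(path)
  bad$portion_g[2] <- 0
  expect_error(load_food_table(write_toy_food_csv(bad)), "fruit1")

  bad <- utils::read.csv(path)
  bad$w_fibre <- 1
  expect_error(load_food_table(write_toy_food_csv(bad)), "fibre")

  bad <- utils::read.csv(path)
  bad$salt_g[1] <- -0.1
  expect_error(load_food_table(write_toy_food_csv(bad)), "veg1")

  bad <- utils::read.csv(path)
  bad <- rbind(bad, bad[1, ])
  expect_error(load_food_table(write_toy_food_csv(bad)), "duplicate")

  bad <- utils::read.csv(path)
  bad$portion_g <- NULL
  expect_error(load_food_table(write_toy_food_csv(bad)), "portion_g")
})

test_that("daily intake converts frequency x portion x weight correctly", {
  ft <- load_food_table(write_toy_food_csv())
  freqs <- pkg_freqs()

  once <- ffq_response("A", "F", 30, 1.6, 55, data.frame(
    item_id = "veg1", frequency = "once a day", portion_multiplier = 1))
  p <- daily_intake(once, ft, freqs)
  expect_equal(p$items$grams_day, 80)
  expect_equal(unname(p$components["vegetables"]), 1)

  never <- ffq_response("A", "F", 30, 1.6, 55, data.frame(
    item_id = c("veg1", "meat1"), frequency = "never",
    portion_multiplier = 1))
  p0 <- daily_intake(never, ft, freqs)
  expect_true(all(p0$components == 0))
  expect_equal(p0$energy_kcal_day, 0)

  weekly <- ffq_response("A", "F", 30, 1.6, 55, data.frame(
    item_id = "fruit1", frequency = "2-3 per week", portion_multiplier = 1))
  pw <- daily_intake(weekly, ft, freqs)
  expect_equal(pw$items$grams_day, 2.5 / 7 * 100, tolerance = 1e-10)
})

test_that("unresolvable items or labels raise informative errors", {
  ft <- load_food_table(write_toy_food_csv())
  r <- ffq_response("A", "M", 40, 1.8, 80, data.frame(
    item_id = "nope", frequency = "once a day", portion_multiplier = 1))
  expect_error(daily_intake(r, ft, pkg_freqs()), "nope")
  r2 <- ffq_response("A", "M", 40, 1.8, 80, data.frame(
    item_id = "veg1", frequency = "sometimes", portion_multiplier = 1))
  expect_error(daily_intake(r2, ft, pkg_freqs()), "sometimes")
})

test_that("percent-of-energy fields follow the 4 and 9 kcal/g factors", {
  foods <- pkg_foods()
  freqs <- pkg_freqs()
  r <- ffq_response("A", "M", 40, 1.8, 80, data.frame(
    item_id = c("cola", "rapeseed_oil", "white_rice"),
    frequency = "once a day", portion_multiplier = 1))
  p <- daily_intake(r, foods, freqs)
  expect_equal(p$free_sugar_pct_energy,
               p$free_sugar_g_day * 4 / p$energy_kcal_day * 100)
  expect_equal(p$pufa_pct_energy,
               p$pufa_g_day * 9 / p$energy_kcal_day * 100)
  expect_equal(unname(p$components["sugars"]), p$free_sugar_pct_energy)
  expect_equal(unname(p$components["healthy_fats"]), p$pufa_pct_energy)
})

test_that("intakes are additive over answer sets and scale with frequency", {
  foods <- pkg_foods()
  freqs <- pkg_freqs()
  a1 <- data.frame(item_id = c("broccoli", "beef_steak", "cola"),
                   frequency = c("once a day", "2-3 per week", "once a day"),
                   portion_multiplier = c(2, 1, 1))
  a2 <- data.frame(item_id = c("salmon", "porridge_oats"),
                   frequency = c("once a week", "4-6 per week"),
                   portion_multiplier = c(1, 1.5))
  mk <- function(ans) ffq_response("A", "F", 30, 1.65, 60, ans)
  p1 <- daily_intake(mk(a1), foods, freqs)
  p2 <- daily_intake(mk(a2), foods, freqs)
  p12 <- daily_intake(mk(rbind(a1, a2)), foods, freqs)
  additive <- setdiff(mahei_components()$name, c("sugars", "healthy_fats"))
  expect_equal(p12$components[additive],
               p1$components[additive] + p2$components[additive])
  expect_equal(p12$energy_kcal_day, p1$energy_kcal_day + p2$energy_kcal_day)
  expect_equal(p12$free_sugar_g_day,
               p1$free_sugar_g_day + p2$free_sugar_g_day)
  expect_equal(p12$pufa_g_day, p1$pufa_g_day + p2$pufa_g_day)

  # doubling every frequency doubles amounts but leaves % energy unchanged
  freqs2 <- freqs
  freqs2$per_day <- freqs2$per_day * 2
  pd <- daily_intake(mk(a1), foods, freqs2)
  expect_equal(pd$energy_kcal_day, 2 * p1$energy_kcal_day)
  expect_equal(pd$components[additive], 2 * p1$components[additive])
  expect_equal(pd$free_sugar_pct_energy, p1$free_sugar_pct_energy)
  expect_equal(pd$pufa_pct_energy, p1$pufa_pct_energy)

  # non-negativity for arbitrary valid inputs
  set.seed(11)
  for (k in 1:20) {
    ans <- data.frame(
      item_id = sample(foods$item_id, 5),
      frequency = sample(freqs$label, 5, replace = TRUE),
      portion_multiplier = sample(c(0.5, 1, 2, 3), 5, replace = TRUE))
    p <- daily_intake(mk(ans), foods, freqs)
    expect_true(all(p$components >= 0))
    expect_true(p$energy_kcal_day >= 0)
    expect_true(all(p$items$grams_day >= 0))
  }
})

test_that("FFQ responses round-trip through JSON", {
  r <- ffq_response("Maya", "F", 33, 1.62, 58,
                    data.frame(item_id = "apple", frequency = "once a day",
                               portion_multiplier = 2),
                    activity = baecke_mid_answers())
  path <- tempfile(fileext = ".json")
  write_ffq(r, path)
  r2 <- read_ffq(path)
  expect_equal(r2$respondent, r$respondent)
  expect_equal(as.data.frame(r2$answers), as.data.frame(r$answers))
  expect_equal(baecke_indices(r2$activity), baecke_indices(r$activity))
})

test_that("respondent validation enforces positive anthropometrics", {
  ans <- data.frame(item_id = "x", frequency = "never",
                    portion_multiplier = 1)
  expect_error(ffq_response("", "F", 30, 1.6, 55, ans), "name")
  expect_error(ffq_response("A", "X", 30, 1.6, 55, ans), "sex")
  expect_error(ffq_response("A", "F", 30, 0, 55, ans), "height")
  expect_error(ffq_response("A", "F", 30, 1.6, -1, ans), "weight")
})
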