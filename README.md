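# enutri

Automated personalised food-based nutrition advice in R.

`enutri` converts a food-frequency questionnaire (FFQ) response into a
personalised dietary report. It is aimed at nutrition researchers building
or evaluating automated dietary-feedback systems: it aggregates categorical
FFQ answers into daily intakes, scores the diet against an 11-component
modified Alternative Healthy Eating Index (m-AHEI), selects the three
weakest components as advice targets, and renders a structured report with
traffic-light feedback, a healthy-weight-range bar and Baecke habitual
physical-activity indices. It also ships the evaluation machinery for such
an engine: a 2^4 factorial scenario factory with a seeded
synthetic-respondent simulator, and aggregation of professional star
ratings and diet-target selections.

## The model

Each m-AHEI component *c* is scored on a 0-100 adherence scale. With target
`best_c` and limit `worst_c`:

* recommended foods (vegetables, fruits, whole grains, dairy, nuts &
  legumes, healthy fats, oily fish):
  `A_c = 100 · clamp((x_c − worst_c) / (best_c − worst_c), 0, 1)`
* foods to limit (free sugars, red & processed meat, salt):
  `A_c = 100 · clamp((worst_c − x_c) / (worst_c − best_c), 0, 1)`
* alcohol: a trapezoid — linear rise over `(0, ideal_low)`, 100 across the
  ideal range, linear fall to 0 at `worst`; non-drinkers receive a partial
  credit (default 25).

Free sugars and PUFA intakes `x_c` are percentages of dietary energy
(4 kcal/g and 9 kcal/g); whole grains and alcohol have sex-specific
cut-points. The overall **Healthy Eating Score** is the unweighted mean of
the 11 adherences, coloured by thirds (red / yellow / green), with the
inverse mapping for foods to limit (red strictly above two-thirds of the
recommended maximum). All cut-points are configuration
(`inst/extdata/mahei_specs.yaml`), versioned and stamped into every report.
The three advice targets are the components with the lowest adherence,
ties broken by display order.

## Worked example

```r
library(enutri)
foods <- load_food_table(system.file("extdata", "foods.csv", package = "enutri"))
specs <- load_mahei_specs()

resp <- ffq_response(
  name = "John", sex = "M", age = 35, height = 1.80, weight = 75,
  answers = data.frame(
    item_id = c("broccoli", "apple", "wholemeal_bread", "semi_skimmed_milk",
                "beef_steak", "cola", "white_rice"),
    frequency = c("once a day", "2-3 per week", "once a day", "once a day",
                  "4-6 per week", "once a day", "once a day"),
    portion_multiplier = c(1, 1, 2, 1, 1, 1, 1)))

profile <- daily_intake(resp, foods)
score <- healthy_eating_score(profile, specs, "M")
print(score)
#> Healthy Eating Score: 30% (red)
#>   Vegetables             recommended  20% (red)
#>   Fruits                 recommended   9% (red)
#>   Whole grains           recommended  76% (green)
#>   Dairy products         recommended  33% (red)
#>   Nuts & legumes         recommended   0% (red)
#>   Healthy fats           recommended   0% (red)
#>   Oily fish              recommended   0% (red)
#>   Sugars                 limit        69% (red)
#>   Red & processed meat   limit        48% (yellow)
#>   Salt                   limit        21% (green)
#>   Alcohol                limit         0% (green)
select_targets(score)
#> [1] "nuts_legumes" "oily_fish"    "healthy_fats"
```

One daily portion of broccoli is 1 of the 5 recommended vegetable servings
(20%); cola pushes free sugars to 69% of the maximum tolerated share of
energy (red, since it exceeds two-thirds); the three components with the
lowest adherence — nuts & legumes, oily fish, healthy fats, all at 0 —
become the advice targets. The full report adds the three-paragraph
messages, weight range and optional activity block:

```r
report <- build_report(resp, foods, specs, load_templates())
cat(render_report(report, "text"))
#> Hi John, this is your personalised report. The following messages present
#> the most important diet changes recommended for you.
#>
#> == nuts_legumes ==
#> You are currently eating 0% of the recommended amount of nuts and legumes.
#> Try adding beans or lentils to soups and stews, and keep a small bag of
#> unsalted nuts handy as a snack.
#> Nuts and legumes provide plant protein, fibre and unsaturated fats, and
#> regular intake is linked with a healthier heart.
#> ...
```

Scenario simulation and evaluation aggregation:

```r
scen <- factorial_scenarios()                       # 16 = 2^4 combinations
r <- simulate_respondent(scen[9, ], foods, specs, seed = 42)
evaluation_design(scen, seed = 1)                   # 64 scenario-evaluations
overall_from_summary(load_professional_evaluation())
#> appropriateness       relevance     suitability
#>             3.6             3.3             3.3
```

A thin command-line wrapper over the same functions lives at
`inst/cli/enutri.R` with subcommands `score`, `report`, `simulate`,
`design` and `evaluate`.

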