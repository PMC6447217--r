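Package: enutri
Title: Automated Personalised Food-Based Nutrition Advice Engine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores food-frequency-questionnaire (FFQ) derived diets against
    an 11-component modified Alternative Healthy Eating Index (m-AHEI),
    selects the three weakest components and composes a structured
    personalised nutrition report with traffic-light feedback, a healthy
    weight range bar and Baecke habitual physical activity indices. Also
    provides a 2^4 factorial evaluation-scenario factory with a seeded
    synthetic-respondent simulator, and aggregation of professional
    star-rating evaluations and target-selection frequencies used to
    validate the automated advice.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    tibble,
    dplyr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
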