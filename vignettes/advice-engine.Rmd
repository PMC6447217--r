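---
title: "The m-AHEI advice engine: model, configuration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The m-AHEI advice engine: model, configuration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enutri)
```

## The problem

Food-frequency questionnaires (FFQs) record how often, and in what portion,
a respondent eats each of a list of foods. `enutri` turns such a record into
automated, personalised, food-based dietary advice: it aggregates the
answers into daily intakes, scores the diet against an 11-component
modified Alternative Healthy Eating Index (m-AHEI), picks the three
components where the diet is weakest, and renders a structured report with
traffic-light feedback, a healthy-weight-range bar and habitual
physical-activity indices. The package also contains the machinery used to
*evaluate* such an engine: a 2^4 factorial scenario factory with a seeded
synthetic-respondent simulator, and aggregation of professional star
ratings and target selections.

## From answers to intakes

Each answer is `(item, frequency category, portion multiplier)`. Frequency
categories are a configurable *dialect* mapping labels to occasions/day;
the packaged defaults use the midpoint-of-range convention (e.g. "2-3 per
week" = 2.5/7) with a mean Gregorian month of 30.44 days for monthly
categories. The portion multiplier is a scalar on the standard portion
(0.5, 1, 2, 3). Then

* occasions/day = frequency multiplier x portion multiplier,
* grams/day = occasions/day x portion grams,
* component intake = sum over items of occasions/day x per-portion weight.

Seven components are food groups with per-item weights (vegetables, fruits,
whole grains, dairy, nuts & legumes, oily fish, red & processed meat); salt
comes from the items' salt content (g/day); alcohol from ethanol grams at
10 g per drink. Free sugars and healthy fats (PUFA) are *energy-based*:
they are expressed as a percentage of dietary energy using 4 kcal/g (sugar)
and 9 kcal/g (PUFA), so they are undefined for a zero-energy diet with
nonzero sugar or PUFA, which the loader rejects. Because they are ratios,
these two fields are scale-invariant: doubling every frequency doubles all
absolute intakes but leaves the % energy fields unchanged (the test suite
asserts this, and additivity holds for every absolute field).

## The scoring model

Each component is scored on a 0-100 **adherence** scale (higher always
better):

* recommended components interpolate linearly from 0 at `worst`
  (conventionally 0 intake) to 100 at `best`, capped beyond;
* foods to limit interpolate from 100 at `best` down to 0 at `worst`;
* alcohol is non-monotone: a trapezoid rising over (0, ideal_low), 100
  across the ideal range, falling to 0 at `worst`, with exact non-drinkers
  given a partial credit (default 25/100), following the convention of the
  AHEI family of indexes.

The overall **Healthy Eating Score** is the unweighted arithmetic mean of
the 11 adherences, shown as a percentage. The *displayed* bar differs from
adherence for foods to limit: it shows percent of the recommended maximum
(capped at 100), so a fuller bar always means more of the food. Colours
follow thirds: red / yellow / green on `[0, 1/3)`, `[1/3, 2/3)`,
`[2/3, 1]` for recommended components and the overall score, inverted for
foods to limit, whose red band starts *strictly above* two-thirds of the
maximum. Displayed percentages are rounded half-up to integers at render
time only; all internal arithmetic is unrounded.

All cut-points live in a versioned YAML config
(`inst/extdata/mahei_specs.yaml`), not in code; the engine is defined over
any valid spec set. The packaged defaults adapt AHEI-2010 cut-points:
vegetables 5 and fruits 4 servings/day, whole grains 75 (F) / 90 (M) g/day,
dairy 3 and nuts & legumes 1 serving/day, PUFA best 10 % energy (worst 2),
oily fish 2 servings/week expressed per day, free sugars best 5 % energy
(worst 25), red & processed meat worst 1.5 servings/day, salt worst
6 g/day, and sex-specific alcohol ranges (F ideal 0.5-1.5 drinks/day,
worst 2.5; M 0.5-2.0, worst 3.5). Two components therefore take sex into
account (whole grains, alcohol) and two take dietary energy into account
(free sugars, PUFA). The config version is stamped into every report.

## The decision engine

The three advice targets are the three components with the lowest
adherence, ordered weakest first. Ranking uses the adherence scale, not the
displayed scale, because the selection is defined over the index itself;
ties are broken by the fixed display order (vegetables first, alcohol
last), a documented deterministic choice. A perfect diet still yields three
(tied-at-100) messages — the always-three rule is part of the report
contract.

Each message has three paragraphs: current status (with the displayed
percentage and the top `n = 3` contributing food items by component-unit
contribution, reported with g/day), a call to action, and the health
benefit. Templates are an editable directory of per-component YAML files
with a small placeholder vocabulary (`{name}`, `{pct}`, `{contributors}`,
`{unit_hint}`); when no mapped item was consumed the contributor sentence
is omitted and the status paragraph stands alone. Recommended components
are always framed as *increase*, foods to limit as *decrease*; the template
loader enforces this.

## Report assembly

The report is a single document: intro (using the respondent's name
verbatim), the three messages, the Healthy Eating Score, the 11 bars in two
labelled groups — "Recommended Foods (The higher the better)" then "Foods
to Limit (The lower the better)" — the healthy weight range, and optionally
the activity block. The weight range converts the healthy BMI band
(18.5-25 kg/m^2) to kilograms for the respondent's height; BMI itself is
never shown. The arrow is the weight's position within the green zone,
clamped to the bar ends with an explicit out-of-range flag rather than
drawn off-bar. JSON rendering is lossless and byte-deterministic for a
fixed report; the timestamp is an injected field so reproducible pipelines
can pin it.

## Physical activity

The 16-item Baecke habitual physical activity questionnaire is scored into
work, sport and leisure indices, each on 1-5: work is
`((6 - sitting) + sum of the other seven work items) / 8` (sitting is
reverse-scored), sport and leisure are means of four items with television
reverse-scored in leisure. The report's low/medium/high activity bands are
thresholds on the total (3-15); the defaults (7, 11) are the tertiles of
the attainable range, shipped as an argument because no canonical banding
exists.

## The scenario simulator

The evaluation design crosses sex, age band (<40 / >40), BMI band (Ideal
18.5-24.9 / Overweight >25) and diet-quality band (m-AHEI <40 / >60) into
16 scenarios; each is evaluated by 2 Registered Dietitians and 2 Registered
Nutritionists, each rater receiving exactly two scenarios (64
scenario-evaluations in all). The assignment is built cyclically after a
seeded shuffle, which guarantees the row/column sums exactly.

The simulator *inverts the scoring model*, which doubles as an independent
test harness for the scorer: per-component adherence fractions are sampled
from band-specific ranges (low band U(0, 0.5); high band U(0.6, 1), with
foods-to-limit sampled near their best, U(0.9, 1)), the implied intakes are
back-solved through a minimal covering set of concentrated food items, and
the resulting occasions/day are snapped onto the categorical frequency
grid. The two %-energy components are inverted against per-sex energy
anchors (2500 kcal/day for men, 2000 for women — standard adult reference
intakes), and a neutral staple tops energy up to the anchor. Because every
food carries energy and the frequency grid is discrete, realised scores
deviate from the sampled fractions; a rejection loop (cap 1000 attempts)
re-samples until the re-scored Healthy Eating Score lands in the scenario's
band, so band membership is guaranteed by construction, not on average. Age
is sampled uniformly in 25-39 / 41-65, height from per-sex normals, and
weight is solved from a BMI sampled inside the scenario's band.

What the simulator does *not* emulate: correlated food choices (real diets
cluster), seasonal variation, under-reporting, and the long tail of a real
FFQ item bank (the packaged table has 30 items, not 157). Passing the
band-recovery tests therefore shows the scorer and simulator are mutually
consistent and the engine behaves correctly across the score range — not
that the packaged food table is nutritionally complete.

## Evaluation aggregation

Professional ratings (1-5 stars on appropriateness, relevance and
suitability) are summarised per scenario as mean ± population SD (n
denominator — the convention under which four ratings of 5, 5, 4, 5
summarise as 4.8 ± 0.4); the overall mean per dimension is the mean of the
per-scenario means, which equals the grand mean when the design is balanced
at 4 ratings per scenario. Target-selection frequencies are counts over all
selections of a source, with "not set" entries excluded from the
denominator; free-text professional targets are canonicalised through an
editable synonym map before concordance is computed (unmapped targets count
as non-matches). The packaged per-scenario evaluation summary
(`inst/extdata/professional_evaluation.csv`) makes all of this runnable
offline.

## Numerical choices and problem sizes

Scoring is closed-form; the only iteration is the simulator's rejection
loop, which in practice accepts within a handful of attempts because the
sampled fractions sit well inside their bands. Property-style tests use
1000 random score vectors for the selection oracle, 1000 random profiles
for the adherence oracle, and 100 seeded respondents per diet band for band
recovery; these sizes give stable checks in well under two minutes on a
single core. Boundary behaviour asserted in tests: colour thresholds at
exactly 100/3 and 200/3, the strict inequality of the limit red band, the
adherence caps beyond `best`/`worst`, and the non-drinker alcohol credit.

## Known limitations

* The packaged m-AHEI cut-points are a documented default configuration,
  not a published standard; any deployment should review them.
* Advice does not consider energy balance, vitamin D, or nutrient-level
  feedback, and does not tailor to age or BMI — the index is purely
  food-based.
* Professional free-text targets are canonicalised only as far as the
  synonym map reaches; thematic analysis of free text is out of scope.
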