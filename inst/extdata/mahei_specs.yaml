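# m-AHEI component scoring configuration (versioned; recorded in every report).
# Cut-points adapted from AHEI-2010. "best" earns adherence 100, "worst"
# earns 0; free sugars and healthy fats (PUFA) are scored as % of dietary
# energy; whole grains and alcohol are sex-specific.
version: "mahei-defaults-1.0"
components:
  - name: vegetables
    category: recommended
    unit: servings/day
    best: 5
    worst: 0
  - name: fruits
    category: recommended
    unit: servings/day
    best: 4
    worst: 0
  - name: whole_grains
    category: recommended
    unit: g/day
    best: {F: 75, M: 90}
    worst: 0
  - name: dairy
    category: recommended
    unit: servings/day
    best: 3
    worst: 0
  - name: nuts_legumes
    category: recommended
    unit: servings/day
    best: 1
    worst: 0
  - name: healthy_fats
    category: recommended
    unit: "% energy"
    energy_based: true
    best: 10
    worst: 2
  - name: oily_fish
    category: recommended
    unit: servings/day       # 2 servings/week expressed per day
    best: 0.2857142857142857
    worst: 0
  - name: sugars
    category: limit
    unit: "% energy"
    energy_based: true
    best: 5
    worst: 25
  - name: red_meat
    category: limit
    unit: servings/day
    best: 0
    worst: 1.5
  - name: salt
    category: limit
    unit: g/day
    best: 0
    worst: 6
  - name: alcohol
    category: limit
    unit: drinks/day          # 1 drink = 10 g ethanol
    ideal_low: {F: 0.5, M: 0.5}
    ideal_high: {F: 1.5, M: 2.0}
    worst: {F: 2.5, M: 3.5}
    nondrinker_credit: 25
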