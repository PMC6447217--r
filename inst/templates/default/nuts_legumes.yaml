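component: nuts_legumes
direction: increase
status: >
  You are currently eating {pct}% of the recommended amount of nuts and
  legumes. {contributors}
action: >
  Try adding beans or lentils to soups and stews, and keep a small bag of
  unsalted nuts handy as a snack.
benefit: >
  Nuts and legumes provide plant protein, fibre and unsaturated fats, and
  regular intake is linked with a healthier heart.
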