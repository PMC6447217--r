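component: vegetables
direction: increase
status: >
  You are currently eating {pct}% of the recommended amount of vegetables.
  {contributors}
action: >
  Try to add an extra portion of vegetables to your main meals - fresh,
  frozen and tinned all count, and a portion is about a handful (80 g).
benefit: >
  Eating more vegetables provides fibre, vitamins and minerals and is linked
  with a lower risk of heart disease and stroke.
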