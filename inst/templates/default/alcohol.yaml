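component: alcohol
direction: decrease
status: >
  Your alcohol intake is at {pct}% of the recommended maximum. {contributors}
action: >
  Try to keep several drink-free days each week and alternate alcoholic
  drinks with water or soft drinks when you do drink.
benefit: >
  Drinking within the recommended limits lowers your risk of liver disease,
  several cancers and high blood pressure.
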