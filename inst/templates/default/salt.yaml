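component: salt
direction: decrease
status: >
  Your salt intake is at {pct}% of the recommended maximum. {contributors}
action: >
  Try tasting food before adding salt, flavouring with herbs and spices
  instead, and checking labels on processed foods, where most salt hides.
benefit: >
  Cutting down on salt helps to lower blood pressure, reducing your risk of
  heart disease and stroke.
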