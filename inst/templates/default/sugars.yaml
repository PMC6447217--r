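component: sugars
direction: decrease
status: >
  Free sugars currently provide {pct}% of the recommended maximum share of
  your energy intake. {contributors}
action: >
  Try cutting down on sugary drinks, confectionery and cakes - swapping a
  sugary drink for water or a sugar-free alternative is a good first step.
benefit: >
  Cutting free sugars helps to protect your teeth and makes it easier to
  keep to a healthy weight.
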