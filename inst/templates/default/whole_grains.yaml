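component: whole_grains
direction: increase
status: >
  You are currently eating {pct}% of the recommended amount of whole grains.
  {contributors}
action: >
  Swap white bread, rice and pasta for wholemeal or wholegrain versions, and
  consider porridge or a wholegrain cereal at breakfast.
benefit: >
  Whole grains are rich in fibre and help to keep your digestive system
  healthy; higher intakes are linked with a lower risk of type 2 diabetes
  and heart disease.
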