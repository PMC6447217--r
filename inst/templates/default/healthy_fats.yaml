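component: healthy_fats
direction: increase
status: >
  Healthy polyunsaturated fats currently make up {pct}% of the recommended
  share of your energy intake. {contributors}
action: >
  Use vegetable oils such as rapeseed or olive oil for cooking and
  dressings, and choose nuts, seeds and oily fish more often.
benefit: >
  Replacing saturated fats with unsaturated fats helps to lower blood
  cholesterol and protects your heart.
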