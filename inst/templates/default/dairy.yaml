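component: dairy
direction: increase
status: >
  You are currently consuming {pct}% of the recommended amount of dairy
  products. {contributors}
action: >
  Try to include milk, yoghurt or cheese each day - a glass of milk, a pot
  of yoghurt or a matchbox-sized piece of cheese each count as a portion.
benefit: >
  Dairy foods are an important source of calcium and protein, which help to
  keep your bones and teeth strong.
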